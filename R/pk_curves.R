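#' Tissue half-life from ln-linear regression
#'
#' Ordinary least squares of `ln(concentration)` on time; the first-order
#' decay constant is `lambda = -slope` and `t_half = ln(2) / lambda`. The
#' half-life is reported only for decaying profiles (`lambda > 0`); otherwise
#' a no-decay flag is set and `t_half` is `NA`.
#'
#' @param time Numeric vector of times (days).
#' @param conc Positive concentrations (any single consistent unit).
#' @return List with `slope`, `lambda` (per day), `t_half` (days), `no_decay`.
#' @examples
#' fit_halflife_lnlinear(c(0, 14), c(100, 50)) # t_half = 14 d
#' @export
fit_halflife_lnlinear <- function(time, conc) {
  stopifnot(length(time) == length(conc))
  if (length(time) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  fit <- stats::lm(log(conc) ~ time)
  slope <- unname(stats::coef(fit)[2])
  lambda <- -slope
  # guard against numerically-zero slopes on flat profiles
  decaying <- lambda > 1e-12
  list(slope = slope, lambda = lambda,
       t_half = if (decaying) log(2) / lambda else NA_real_,
       no_decay = !decaying)
}

# Deterministic multi-start bounded nonlinear least squares via nlsLM.
# starts: data.frame of start values; fn: formula; data: data.frame.
multistart_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(starts[i, ]),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Three-parameter log(inhibitor) vs response fit
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^(x - log10_ec50))` with
#' `x = log10(concentration)` and the Hill slope fixed at -1 (inhibition).
#' Emax is reported as the maximal fitted reduction, `top - bottom`
#' (equal to `100 - bottom` when the control level is 100%). Initialization
#' uses a deterministic multi-start grid (bottom at 0 and the minimum
#' response, top at the maximum response, log10 EC50 over the concentration
#' range).
#'
#' @param conc Positive concentrations (nM); at least 4 distinct values.
#' @param response Responses (% of control), spanning a decline.
#' @return List with `bottom`, `top`, `log10_ec50`, `ec50`, `emax`, `rss`,
#'   `converged`.
#' @export
fit_log_inhibitor_response_3p <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  if (length(unique(conc)) < 4L) {
    stop("need >= 4 distinct concentrations", call. = FALSE)
  }
  if (stats::sd(response) == 0) {
    stop("responses show no decline; cannot fit an inhibition curve",
         call. = FALSE)
  }
  d <- data.frame(x = log10(conc), y = response)
  starts <- expand.grid(
    bottom = c(0, min(response)),
    top = max(response),
    le50 = seq(min(d$x), max(d$x), length.out = 4)
  )
  best <- multistart_nls(
    y ~ bottom + (top - bottom) / (1 + 10^(x - le50)), d, starts,
    lower = c(bottom = -Inf, top = -Inf, le50 = min(d$x) - 3),
    upper = c(bottom = Inf, top = Inf, le50 = max(d$x) + 3))
  if (is.null(best)) {
    stop("dose-response fit failed to converge from all starts", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
       log10_ec50 = unname(cf["le50"]), ec50 = 10^unname(cf["le50"]),
       emax = unname(cf["top"] - cf["bottom"]), rss = best$rss,
       converged = TRUE)
}

#' RISC-loading ratio
#'
#' siRNA level relative to the ubiquitous miR-16 level in the same Ago2
#' immunoprecipitate. Vectorized.
#'
#' @param sirna_level,mir16_level Numeric; `mir16_level` must be > 0.
#' @return `sirna_level / mir16_level`.
#' @export
risc_load_ratio <- function(sirna_level, mir16_level) {
  if (any(mir16_level <= 0)) {
    stop("miR-16 level must be > 0", call. = FALSE)
  }
  sirna_level / mir16_level
}

#' Quantify samples against a log-linear standard curve
#'
#' Fits `signal ~ log10(concentration)` to spiked standards (typically an
#' 8-point curve, as in stem-loop RT-qPCR siRNA quantification) and
#' back-interpolates sample concentrations. Samples whose signal falls outside
#' the standards' signal range are flagged `extrapolated` but still returned.
#'
#' @param std_conc Known standard concentrations (> 0, >= 3 values).
#' @param std_signal Measured standard signals.
#' @param sample_signal Measured sample signals.
#' @return Data.frame with `signal`, `conc`, `extrapolated`.
#' @export
quantify_from_standard_curve <- function(std_conc, std_signal, sample_signal) {
  stopifnot(length(std_conc) == length(std_signal), all(std_conc > 0))
  if (length(std_conc) < 3L) stop("need >= 3 standards", call. = FALSE)
  fit <- stats::lm(std_signal ~ log10(std_conc))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps^0.5) {
    stop("degenerate standard curve (zero slope)", call. = FALSE)
  }
  intercept <- unname(stats::coef(fit)[1])
  data.frame(
    signal = sample_signal,
    conc = 10^((sample_signal - intercept) / slope),
    extrapolated = sample_signal < min(std_signal) | sample_signal > max(std_signal)
  )
}

#' Specific binding with Hill slope fit
#'
#' Least squares of `signal = bmax * X^h / (kd^h + X^h)` over ligand
#' concentrations X, as used for antibody-receptor ELISA binding curves.
#'
#' @param conc Positive ligand concentrations (>= 5 values).
#' @param signal Background-corrected signals.
#' @return List with `bmax`, `kd`, `hill_h`, `rss`, `converged`.
#' @export
fit_specific_binding_hill <- function(conc, signal) {
  stopifnot(length(conc) == length(signal))
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(conc)) < 5L) {
    stop("need >= 5 distinct concentrations", call. = FALSE)
  }
  d <- data.frame(x = conc, y = signal)
  starts <- expand.grid(
    bmax = max(signal) * c(1, 1.5),
    kd = unname(stats::quantile(conc, c(0.25, 0.5, 0.75))),
    h = c(0.8, 1.5)
  )
  best <- multistart_nls(
    y ~ bmax * x^h / (kd^h + x^h), d, starts,
    lower = c(bmax = 0, kd = .Machine$double.xmin, h = 0.1),
    upper = c(bmax = Inf, kd = Inf, h = 10))
  if (is.null(best)) {
    stop("Hill binding fit failed to converge from all starts", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  list(bmax = unname(cf["bmax"]), kd = unname(cf["kd"]),
       hill_h = unname(cf["h"]), rss = best$rss, converged = TRUE)
}
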