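#' Mann-Whitney AUC effect size between two samples
#'
#' Probability that a value from `x` is below a value from `y`, with ties
#' counted half:
#' `AUC = (#\{x_i < y_j\} + 0.5 #\{x_i = y_j\}) / (nm)`.
#' Applied to log2 fold-changes with `x` the seed-matched genes and `y` the
#' background, siRNA-driven repression of matched genes yields AUC > 0.5.
#'
#' Computed via the rank formula, which is exactly the pair enumeration.
#'
#' @param x,y Non-empty numeric vectors (finite values).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_effect_size(c(1, 2), c(2, 3)) # 0.875
#' @export
auc_effect_size <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  # U counts pairs with x > y plus half-ties; AUC is its complement.
  u_x <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  1 - u_x / (n * m)
}

#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' D is the supremum over all breakpoints of the absolute difference between
#' the two empirical CDFs. The p-value uses the asymptotic Kolmogorov
#' distribution at effective sample size `ne = nm/(n+m)`:
#' `p = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 ne D^2)`, clamped to (0, 1].
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `D`, `p`, `n`, `m`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  m <- length(y)
  breaks <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(breaks)
  fy <- stats::ecdf(y)(breaks)
  D <- max(abs(fx - fy))
  ne <- n * m / (n + m)
  t2 <- ne * D^2
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t2))
  p <- min(1, max(p, .Machine$double.xmin))
  list(D = D, p = p, n = n, m = m)
}

#' Seed-based off-target profile per seed length-class
#'
#' For each seed class, compares the log2 fold-change distribution of
#' expressed genes with a seed-match hit against the simulated-siRNA
#' background set, reporting the Mann-Whitney AUC and the two-sample KS test.
#' Genes present in both a matched set and the background are removed from the
#' background for that class. A class with no matched gene is reported with
#' `n_matched = 0` and `NA` statistics rather than an error.
#'
#' @param fc Named numeric vector of log2 fold-changes for expressed genes
#'   (names are gene ids; finite values).
#' @param matches Seed-match table from [scan_utr_matches()].
#' @param background Character vector of background gene ids (from
#'   [build_simulated_background()]).
#' @return Data.frame with one row per class: `class`, `n_matched`,
#'   `n_background`, `auc`, `ks_D`, `ks_p`.
#' @export
seed_offtarget_profile <- function(fc, matches, background) {
  stopifnot(is.numeric(fc), !is.null(names(fc)))
  fc <- fc[is.finite(fc)]
  classes <- sort(unique(matches$class))
  bg_all <- intersect(background, names(fc))
  rows <- lapply(classes, function(cl) {
    matched <- matches$gene_id[matches$class == cl & matches$hit]
    matched <- intersect(matched, names(fc))
    bg <- setdiff(bg_all, matched)
    if (length(matched) == 0L || length(bg) == 0L) {
      return(data.frame(class = cl, n_matched = length(matched),
                        n_background = length(bg), auc = NA_real_,
                        ks_D = NA_real_, ks_p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    x <- unname(fc[matched])
    y <- unname(fc[bg])
    ks <- ks_two_sample(x, y)
    data.frame(class = cl, n_matched = length(matched),
               n_background = length(bg), auc = auc_effect_size(x, y),
               ks_D = ks$D, ks_p = ks$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
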