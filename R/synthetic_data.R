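# Synthetic-data generators. Every generator is a pure function of its
# arguments: the same seed yields byte-identical output. Defaults mirror the
# study conditions the pipeline was designed around (a 70-guide screening
# library, 4 target + 2 housekeeping qPCR genes, 10 simulated background
# siRNAs, 8-point standard curves, muscle half-life around 17 days,
# sub-nanomolar EC50).

#' Simulate a 3'UTR database with planted seed-match sites
#'
#' UTRs are drawn with i.i.d. uniform nucleotides; a chosen fraction of genes
#' receives one implanted reverse-complement site of the designated guide's
#' 6mer seed at a random position. The registry lists exactly which genes
#' carry implants, enabling recovery assertions downstream.
#'
#' @param n_genes Number of UTR records.
#' @param utr_length Mean UTR length (nt); lengths are drawn uniformly within
#'   +/- 20% of this value.
#' @param implant_fraction Fraction of genes receiving an implanted site.
#' @param guide Guide-strand RNA sequence whose 6mer seed is implanted
#'   (required when `implant_fraction > 0`).
#' @param six_mer 6mer window convention, as in [extract_seeds()].
#' @param seed Integer RNG seed.
#' @return List with `utrs` (named character vector) and `registry`
#'   (character vector of implanted gene ids).
#' @export
sim_utr_database <- function(n_genes = 2000, utr_length = 600,
                             implant_fraction = 0, guide = NULL,
                             six_mer = "2_7", seed = 1) {
  stopifnot(n_genes >= 1, utr_length >= 20, implant_fraction >= 0,
            implant_fraction <= 1)
  site <- NULL
  if (implant_fraction > 0) {
    if (is.null(guide)) stop("guide is required to implant sites", call. = FALSE)
    s <- extract_seeds(guide, six_mer = six_mer)
    site <- seed_site_dna(s$seed[s$class == "6mer"])
  }
  withr::with_seed(seed, {
    lens <- sample(seq(round(utr_length * 0.8), round(utr_length * 1.2)),
                   n_genes, replace = TRUE)
    utrs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(utrs) <- sprintf("gene%05d", seq_len(n_genes))
    registry <- character(0)
    if (!is.null(site)) {
      n_implant <- round(implant_fraction * n_genes)
      registry <- sort(sample(names(utrs), n_implant))
      for (g in registry) {
        L <- nchar(utrs[[g]])
        if (nchar(site) > L) stop("implant longer than UTR", call. = FALSE)
        pos <- sample(L - nchar(site) + 1L, 1L)
        substr(utrs[[g]], pos, pos + nchar(site) - 1L) <- site
      }
    }
    list(utrs = utrs, registry = registry)
  })
}

#' Simulate a two-group count matrix with planted fold-changes
#'
#' Negative-binomial counts for a control group; planted genes' means are
#' shifted by `lfc` (log2) in the treated group. Baseline means are drawn
#' log-normally; planted genes are drawn among moderately expressed genes
#' (baseline mean >= 20 counts), reflecting that induced signature genes are
#' robustly expressed.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param planted Either gene ids to plant on, a count of genes to plant, or
#'   0 for a null experiment.
#' @param lfc Planted log2 fold-change (treated vs control).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param seed Integer RNG seed.
#' @return List with `counts` (genes x samples integer matrix), `group`
#'   (character vector, `"control"`/`"treated"`), `true_lfc` (named numeric),
#'   `planted` (gene ids).
#' @export
sim_expression_experiment <- function(n_genes = 2000, n_per_group = 4,
                                      planted = 0, lfc = 0, dispersion = 0.1,
                                      seed = 1) {
  stopifnot(n_genes >= 1, n_per_group >= 2, dispersion > 0)
  withr::with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    mu <- exp(stats::rnorm(n_genes, 4, 1.2))
    names(mu) <- genes
    if (is.character(planted)) {
      planted_genes <- intersect(planted, genes)
    } else if (is.numeric(planted) && planted > 0) {
      eligible <- genes[mu >= 20]
      planted_genes <- sort(sample(eligible, min(planted, length(eligible))))
    } else {
      planted_genes <- character(0)
    }
    true_lfc <- stats::setNames(rep(0, n_genes), genes)
    true_lfc[planted_genes] <- lfc
    group <- rep(c("control", "treated"), each = n_per_group)
    size <- 1 / dispersion
    counts <- matrix(0L, n_genes, 2 * n_per_group,
                     dimnames = list(genes, paste0("s", seq_len(2 * n_per_group))))
    for (j in seq_along(group)) {
      mu_j <- if (group[j] == "treated") mu * 2^true_lfc else mu
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = size)
    }
    list(counts = counts, group = group, true_lfc = true_lfc,
         planted = planted_genes)
  })
}

#' Simulate a qPCR Ct table with sporadic burst-like target expression
#'
#' Housekeeping Cts are Normal(20, 0.2^2). Target-gene Cts sit at a high
#' baseline (low expression) with well-level Gaussian noise; with probability
#' `burst_prob` a well's targets "burst" (drop by `burst_magnitude` cycles),
#' emulating the sporadic, highly variable expression of DUX4-regulated genes.
#' Treated wells add `knockdown_dct` cycles to every target gene.
#'
#' @param n_mock,n_treated Wells per condition.
#' @param target_genes,hk_genes Gene column names (defaults: 4 targets,
#'   2 housekeeping).
#' @param target_baseline Baseline target Ct (default 30 cycles).
#' @param target_sd Well-level target Ct noise SD (default 0.3 cycles).
#' @param burst_prob Probability a well bursts (default 0.2).
#' @param burst_magnitude Cycles dropped in a burst (default 3).
#' @param knockdown_dct Knockdown effect in cycles added to treated targets
#'   (default 2, i.e. a 75% reduction).
#' @param seed Integer RNG seed.
#' @return A Ct data.frame suitable for [fshd_composite()].
#' @export
sim_ct_table <- function(n_mock = 8, n_treated = 4,
                         target_genes = c("MBD3L2", "ZSCAN4", "LEUTX", "KHDC1L"),
                         hk_genes = c("AHSA1", "RPL27"),
                         target_baseline = 30, target_sd = 0.3,
                         burst_prob = 0.2, burst_magnitude = 3,
                         knockdown_dct = 2, seed = 1) {
  stopifnot(n_mock >= 1, n_treated >= 1, burst_prob >= 0, burst_prob <= 1)
  withr::with_seed(seed, {
    n <- n_mock + n_treated
    condition <- rep(c("mock", "treated"), c(n_mock, n_treated))
    burst <- stats::rbinom(n, 1, burst_prob) * burst_magnitude
    ct <- data.frame(sample = sprintf("w%03d", seq_len(n)),
                     condition = condition, stringsAsFactors = FALSE)
    for (g in target_genes) {
      ct[[g]] <- target_baseline - burst +
        stats::rnorm(n, 0, target_sd) +
        ifelse(condition == "treated", knockdown_dct, 0)
    }
    for (g in hk_genes) {
      ct[[g]] <- stats::rnorm(n, 20, 0.2)
    }
    ct
  })
}

#' Simulate a tissue concentration-time series
#'
#' `c(t) = c0 * exp(-lambda * t) * exp(eps)`, `eps ~ Normal(0, cv^2)`
#' (log-normal multiplicative noise).
#'
#' @param c0 Initial concentration.
#' @param t_half True half-life (days, default 17); `lambda = ln(2)/t_half`.
#' @param times Sampling times (days).
#' @param n_per_time Replicates (animals) per timepoint.
#' @param cv Log-scale noise SD (default 0.2).
#' @param group,tissue Labels carried into the output.
#' @param seed Integer RNG seed.
#' @return Data.frame with `time`, `conc`, `group`, `tissue`.
#' @export
sim_conc_time <- function(c0 = 100, t_half = 17,
                          times = c(7, 14, 28, 56), n_per_time = 5,
                          cv = 0.2, group = "dose1", tissue = "gastrocnemius",
                          seed = 1) {
  stopifnot(c0 > 0, t_half > 0, cv >= 0)
  lambda <- log(2) / t_half
  withr::with_seed(seed, {
    time <- rep(times, each = n_per_time)
    conc <- c0 * exp(-lambda * time) * exp(stats::rnorm(length(time), 0, cv))
    data.frame(time = time, conc = conc, group = group, tissue = tissue,
               stringsAsFactors = FALSE)
  })
}

#' Simulate dose-response data from the 3-parameter inhibition curve
#'
#' Responses from
#' `bottom + (top - bottom) / (1 + 10^(log10(conc) - log10_ec50))` plus
#' Gaussian noise. Defaults reflect a sub-nanomolar inhibitor reducing a
#' composite score from 100% to a few percent.
#'
#' @param bottom,top,log10_ec50 True curve parameters (defaults 4, 100,
#'   log10(0.3 nM)).
#' @param conc Concentrations (nM); default an 8-point half-log series.
#' @param n_rep Replicates per concentration.
#' @param noise_sd Gaussian response noise SD (% points).
#' @param seed Integer RNG seed.
#' @return Data.frame with `conc`, `response`, `replicate`.
#' @export
sim_dose_response <- function(bottom = 4, top = 100, log10_ec50 = log10(0.3),
                              conc = 10^seq(-3, 2, length.out = 8), n_rep = 3,
                              noise_sd = 0, seed = 1) {
  stopifnot(all(conc > 0), n_rep >= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    cc <- rep(conc, each = n_rep)
    mu <- bottom + (top - bottom) / (1 + 10^(log10(cc) - log10_ec50))
    data.frame(conc = cc,
               response = mu + stats::rnorm(length(cc), 0, noise_sd),
               replicate = rep(seq_len(n_rep), times = length(conc)))
  })
}
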