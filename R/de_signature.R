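#' log2 counts-per-million matrix
#'
#' `log2((count + pseudocount) / (library_size + 2 * pseudocount) * 1e6)`,
#' where library size is the per-sample column sum of raw counts. With
#' `pseudocount = 0`, zero counts map to `-Inf`.
#'
#' @param counts Non-negative integer genes x samples matrix.
#' @param pseudocount Non-negative prior count (default 0.5).
#' @return Numeric matrix of the same dimension.
#' @export
log2cpm_matrix <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs library size > 0", call. = FALSE)
  log2(sweep(counts + pseudocount, 2, lib + 2 * pseudocount, "/") * 1e6)
}

#' Low-expression filter on a log2CPM matrix
#'
#' Retains genes whose row-mean log2CPM is at least `threshold`; genes with
#' average log2CPM strictly below the threshold (default -3) are eliminated
#' before differential expression analysis.
#'
#' @param log2cpm Genes x samples log2CPM matrix with rownames.
#' @param threshold Cutoff (default -3); `-Inf` retains everything, `Inf`
#'   retains nothing.
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(log2cpm, threshold = -3) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, !is.na(threshold))
  log2cpm <- as.matrix(log2cpm)
  rownames(log2cpm)[rowMeans(log2cpm) >= threshold]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in p-rank and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (FDR) of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Plain two-group Welch differential-expression table
#'
#' Plumbing for synthetic end-to-end tests only: per-gene Welch t-test on
#' log2CPM values with BH adjustment. Not equivalent to a moderated
#' (empirical-Bayes) fit on real data.
#'
#' @param counts Genes x samples count matrix with rownames and colnames.
#' @param group Factor/character per sample with exactly two levels.
#' @param treated Level treated as the numerator of the fold-change (default
#'   the second sorted level).
#' @param pseudocount Passed to [log2cpm_matrix()].
#' @return A DE table data.frame: `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `avg_log2cpm`.
#' @export
welch_de <- function(counts, group, treated = NULL, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("group must have exactly two levels", call. = FALSE)
  if (is.null(treated)) treated <- lev[2]
  control <- setdiff(lev, treated)
  lc <- log2cpm_matrix(counts, pseudocount)
  a <- lc[, group == treated, drop = FALSE]
  b <- lc[, group == control, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(p)] <- 1
  data.frame(gene_id = rownames(counts), log2fc = ma - mb, p_value = p,
             fdr = bh_fdr(p), avg_log2cpm = rowMeans(lc),
             stringsAsFactors = FALSE, row.names = NULL)
}

check_de_table <- function(de, what = "DE table") {
  need <- c("gene_id", "log2fc", "fdr")
  missing <- setdiff(need, names(de))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Disease/treatment signature concordance counts
#'
#' Counts how a gene signature dysregulated in disease responds to treatment.
#' Upregulated arm: signature genes with disease `log2fc >= lfc_threshold` and
#' `fdr < fdr_threshold`; of those, genes with negative treatment log2fc
#' (suppressed); of those, genes with treatment `fdr < fdr_threshold`
#' (suppressed significantly). The downregulated arm mirrors this with
#' `log2fc <= -lfc_threshold` and positive treatment log2fc (reversed).
#'
#' @param disease_de,treatment_de DE tables (columns `gene_id`, `log2fc`,
#'   `fdr`).
#' @param signature Character vector of signature gene ids, or `NULL` to count
#'   over all genes shared by the two tables.
#' @param lfc_threshold,fdr_threshold Printed thresholds, defaults 1 and 0.05.
#' @return Data.frame with `direction` (`"up"`, `"down"`) and counts
#'   `n_disease`, `n_responding`, `n_responding_significant`.
#' @export
signature_concordance <- function(disease_de, treatment_de, signature = NULL,
                                  lfc_threshold = 1, fdr_threshold = 0.05) {
  check_de_table(disease_de, "disease DE table")
  check_de_table(treatment_de, "treatment DE table")
  universe <- intersect(disease_de$gene_id, treatment_de$gene_id)
  if (!is.null(signature)) universe <- intersect(universe, signature)
  d <- disease_de[match(universe, disease_de$gene_id), ]
  t <- treatment_de[match(universe, treatment_de$gene_id), ]
  arm <- function(up) {
    in_disease <- if (up) {
      d$log2fc >= lfc_threshold & d$fdr < fdr_threshold
    } else {
      d$log2fc <= -lfc_threshold & d$fdr < fdr_threshold
    }
    responding <- in_disease & (if (up) t$log2fc < 0 else t$log2fc > 0)
    significant <- responding & t$fdr < fdr_threshold
    data.frame(direction = if (up) "up" else "down",
               n_disease = sum(in_disease),
               n_responding = sum(responding),
               n_responding_significant = sum(significant),
               stringsAsFactors = FALSE)
  }
  rbind(arm(TRUE), arm(FALSE))
}

#' Select a DUX4-responsive gene panel
#'
#' Genes satisfying all of: upregulated in the disease model
#' (`log2fc > lfc_threshold`, strict) and robustly expressed
#' (`tpm > tpm_threshold`, strict). This mirrors the selection of the 56-gene
#' murine NanoString panel (>35 TPM, log2FC > 1.5).
#'
#' @param tpm Named numeric vector of per-gene TPM in the disease model.
#' @param de DE table with `gene_id` and `log2fc`.
#' @param tpm_threshold,lfc_threshold Strict lower bounds (defaults 35, 1.5).
#' @return Character vector of selected gene ids.
#' @export
select_dux4_panel <- function(tpm, de, tpm_threshold = 35, lfc_threshold = 1.5) {
  stopifnot(is.numeric(tpm), !is.null(names(tpm)))
  if (!all(c("gene_id", "log2fc") %in% names(de))) {
    stop("DE table is missing column(s): gene_id/log2fc", call. = FALSE)
  }
  shared <- intersect(names(tpm), de$gene_id)
  lfc <- de$log2fc[match(shared, de$gene_id)]
  shared[tpm[shared] > tpm_threshold & lfc > lfc_threshold]
}
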