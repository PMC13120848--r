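# Ct tables are plain data.frames: metadata columns `sample`, `condition`
# ("treated"/"mock"), optional `group`, plus one numeric column per gene.
# Undetermined Cts are NA.

check_ct_table <- function(ct, genes) {
  stopifnot(is.data.frame(ct))
  if (!"condition" %in% names(ct)) {
    stop("Ct table needs a 'condition' column (treated/mock)", call. = FALSE)
  }
  missing <- setdiff(genes, names(ct))
  if (length(missing)) {
    stop("Ct table is missing gene column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

row_mean_ct <- function(ct, genes) {
  rowMeans(as.matrix(ct[, genes, drop = FALSE]))
}

#' FSHD composite DUX4-activity score from a qPCR Ct table
#'
#' DUX4 itself is expressed sporadically and at very low levels, so DUX4
#' activity is read out from downstream DUX4-regulated genes. Per well:
#' `dCt = mean Ct(4 target genes) - mean Ct(2 housekeeping genes)`;
#' `ddCt = dCt - mean dCt(mock wells)`; `composite = 2^(-ddCt) * 100` (% of
#' mock). Wells with an undetermined (NA) Ct in a required gene are excluded
#' with a warning, or raise an error under `strict = TRUE`.
#'
#' @param ct Ct data.frame (see Details in the package vignette): columns
#'   `condition` (`"treated"`/`"mock"`), optional `sample`/`group`, plus one
#'   numeric Ct column per gene.
#' @param target_genes Character vector of DUX4-regulated target gene columns
#'   (typically 4: MBD3L2, ZSCAN4, LEUTX, KHDC1L).
#' @param hk_genes Housekeeping gene columns (typically 2: AHSA1, RPL27).
#' @param strict Error (rather than exclude) on undetermined Cts.
#' @return List with `per_well` (data.frame: metadata, `delta_ct`,
#'   `delta_delta_ct`, `composite_percent`) and `summary` (per condition/group:
#'   n, mean, sd, geometric mean of the composite).
#' @examples
#' ct <- data.frame(condition = c("mock", "mock", "treated"),
#'                  G1 = c(28, 29, 30.5), G2 = c(29, 30, 31.5),
#'                  G3 = c(30, 31, 32.5), G4 = c(31, 32, 33.5),
#'                  HK1 = c(20, 20, 20), HK2 = c(21, 21, 21))
#' fshd_composite(ct, c("G1", "G2", "G3", "G4"), c("HK1", "HK2"))
#' @export
fshd_composite <- function(ct, target_genes, hk_genes, strict = FALSE) {
  check_ct_table(ct, c(target_genes, hk_genes))
  if (!any(ct$condition == "mock")) {
    stop("Ct table needs at least one mock (reference) well", call. = FALSE)
  }
  need <- c(target_genes, hk_genes)
  bad <- !stats::complete.cases(ct[, need, drop = FALSE])
  if (any(bad)) {
    if (strict) {
      stop(sum(bad), " well(s) have undetermined Ct in required genes",
           call. = FALSE)
    }
    warning("excluding ", sum(bad), " well(s) with undetermined Ct")
    ct <- ct[!bad, , drop = FALSE]
  }
  dct <- row_mean_ct(ct, target_genes) - row_mean_ct(ct, hk_genes)
  ref <- mean(dct[ct$condition == "mock"])
  ddct <- dct - ref
  per_well <- cbind(
    ct[, intersect(c("sample", "condition", "group"), names(ct)), drop = FALSE],
    delta_ct = dct, delta_delta_ct = ddct,
    composite_percent = 2^(-ddct) * 100
  )
  key <- interaction(per_well$condition,
                     if ("group" %in% names(per_well)) per_well$group else "",
                     drop = TRUE)
  summary <- do.call(rbind, lapply(split(per_well, key), function(d) {
    data.frame(condition = d$condition[1],
               group = if ("group" %in% names(d)) d$group[1] else NA_character_,
               n = nrow(d),
               mean = mean(d$composite_percent),
               sd = stats::sd(d$composite_percent),
               geomean = geomean(d$composite_percent),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(per_well = per_well, summary = summary)
}

#' Single-gene relative expression by the 2^(-ddCt) method
#'
#' Livak relative quantification of one gene against a reference gene,
#' relative to the mean dCt of a control group (e.g. murine Col3a1/Fn1/Tgfb1
#' against Ppib, relative to the TMX-only group).
#'
#' @param ct Ct data.frame with a `group` column plus gene columns.
#' @param gene,reference_gene Gene and reference-gene column names.
#' @param control_group Value of `group` defining the reference condition.
#' @param strict As in [fshd_composite()].
#' @return Data.frame of per-well metadata plus `relative_expression`.
#' @export
relative_expression_ddct <- function(ct, gene, reference_gene, control_group,
                                     strict = FALSE) {
  stopifnot(is.data.frame(ct), "group" %in% names(ct))
  missing <- setdiff(c(gene, reference_gene), names(ct))
  if (length(missing)) {
    stop("Ct table is missing gene column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!any(ct$group == control_group)) {
    stop("control group '", control_group, "' has no wells", call. = FALSE)
  }
  bad <- !stats::complete.cases(ct[, c(gene, reference_gene), drop = FALSE])
  if (any(bad)) {
    if (strict) stop(sum(bad), " well(s) have undetermined Ct", call. = FALSE)
    warning("excluding ", sum(bad), " well(s) with undetermined Ct")
    ct <- ct[!bad, , drop = FALSE]
  }
  dct <- ct[[gene]] - ct[[reference_gene]]
  ref <- mean(dct[ct$group == control_group])
  cbind(ct[, intersect(c("sample", "condition", "group"), names(ct)),
           drop = FALSE],
        relative_expression = 2^(-(dct - ref)))
}

#' Geometric-mean composite of a gene panel, as percent of a reference group
#'
#' Per sample, the geometric mean across panel genes of `value + floor`;
#' composites are scaled so the reference group's mean is 100%. Used for the
#' 4-gene murine DUX4-regulated panel (Wfdc3, Ilvbl, Slc15a2, Sord) and the
#' 56-gene NanoString panel, relative to vehicle-treated animals.
#'
#' @param panel Data.frame with a `group` column plus numeric gene columns
#'   (normalized expression, non-negative).
#' @param genes Panel gene column names.
#' @param reference_group Value of `group` used as the 100% reference.
#' @param floor Non-negative value added before taking logs (default 0; with
#'   zeros present a positive floor such as 0.5 counts is required).
#' @return Data.frame of per-sample metadata plus `geomean` and
#'   `composite_percent`.
#' @export
geometric_mean_composite <- function(panel, genes, reference_group, floor = 0) {
  stopifnot(is.data.frame(panel), "group" %in% names(panel), floor >= 0)
  missing <- setdiff(genes, names(panel))
  if (length(missing)) {
    stop("panel is missing gene column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!any(panel$group == reference_group)) {
    stop("reference group '", reference_group, "' has no samples", call. = FALSE)
  }
  m <- as.matrix(panel[, genes, drop = FALSE]) + floor
  if (any(m <= 0)) {
    stop("non-positive panel values after flooring; use a positive `floor`",
         call. = FALSE)
  }
  gm <- exp(rowMeans(log(m)))
  ref <- mean(gm[panel$group == reference_group])
  cbind(panel[, intersect(c("sample", "group"), names(panel)), drop = FALSE],
        geomean = gm, composite_percent = 100 * gm / ref)
}

#' Construct a NanoString-style run
#'
#' @param counts Numeric probes x samples matrix of raw counts (rownames =
#'   probe ids, colnames = sample ids).
#' @param probe_class Character vector (length nrow) over
#'   `"endogenous"`, `"positive"`, `"housekeeping"`, `"dux4"`.
#' @param calibrator Logical vector (length ncol) flagging calibrator samples.
#' @return A list of class `nanostring_run`.
#' @export
nanostring_run <- function(counts, probe_class,
                           calibrator = rep(FALSE, ncol(counts))) {
  counts <- as.matrix(counts)
  stopifnot(length(probe_class) == nrow(counts),
            length(calibrator) == ncol(counts),
            all(counts >= 0))
  ok <- c("endogenous", "positive", "housekeeping", "dux4")
  if (!all(probe_class %in% ok)) {
    stop("probe_class entries must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (sum(probe_class == "positive") < 2 || sum(probe_class == "housekeeping") < 1) {
    stop("need >= 2 positive-control and >= 1 housekeeping probe", call. = FALSE)
  }
  structure(list(counts = counts, probe_class = probe_class,
                 calibrator = calibrator), class = "nanostring_run")
}

#' Normalize a NanoString-style run
#'
#' Three sequential scalings: (1) per-sample positive-control factor (platform
#' geometric mean of per-sample positive-control geomeans divided by this
#' sample's geomean), (2) the same construction over housekeeping probes,
#' (3) a per-probe calibrator factor (ratio to the mean over flagged
#' calibrator samples), skipped when no calibrator is flagged. The DUX4 signal
#' is the arithmetic mean of the DUX4-class probes after normalization.
#'
#' @param run A [nanostring_run()].
#' @return List with `normalized` (probes x samples matrix), `dux4`
#'   (per-sample mean of DUX4 probes, or NULL when absent), and the per-sample
#'   `positive_factor` / `housekeeping_factor` applied.
#' @export
nanostring_normalize <- function(run) {
  stopifnot(inherits(run, "nanostring_run"))
  m <- run$counts
  scale_by <- function(m, rows) {
    g <- apply(m[rows, , drop = FALSE], 2, geomean)
    if (any(g == 0) || any(!is.finite(g))) {
      stop("zero or non-finite control geometric mean; cannot normalize",
           call. = FALSE)
    }
    factor <- geomean(g) / g
    list(m = sweep(m, 2, factor, "*"), factor = factor)
  }
  pos <- scale_by(m, run$probe_class == "positive")
  hk <- scale_by(pos$m, run$probe_class == "housekeeping")
  m <- hk$m
  if (any(run$calibrator)) {
    cal <- rowMeans(m[, run$calibrator, drop = FALSE])
    if (any(cal == 0)) stop("zero calibrator mean for some probe", call. = FALSE)
    m <- sweep(m, 1, cal, "/")
  }
  dux4 <- if (any(run$probe_class == "dux4")) {
    colMeans(m[run$probe_class == "dux4", , drop = FALSE])
  }
  list(normalized = m, dux4 = dux4,
       positive_factor = pos$factor, housekeeping_factor = hk$factor)
}
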