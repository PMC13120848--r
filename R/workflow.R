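#' Run the synthetic end-to-end workflow
#'
#' Chains the pipeline stages in dependency order on synthetic data:
#' simulate a 3'UTR database and expression experiment, extract the test
#' guide's seeds, scan UTRs, build the simulated-siRNA background, compute
#' the per-class off-target profile, simulate and score a Ct table, and fit
#' the PK/PD curves. All stage outputs are written as tab-separated tables
#' plus a machine-readable JSON summary; reruns with the same configuration
#' are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer RNG seed; per-stage seeds are derived from it.
#' @param guide Test siRNA guide strand (RNA, 5' to 3'). The default is the
#'   reverse complement of the human siDUX4.6 target site.
#' @param n_genes UTR/expression genes to simulate.
#' @param implant_fraction Fraction of genes receiving a planted 6mer site.
#' @param planted_lfc Planted log2FC on seed-matched genes in the expression
#'   experiment.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "scan", "offtarget", "composite", "pk")`; later stages
#'   require earlier ones.
#' @return List with `status` (0 on success), `manifest` (written files) and
#'   `summary` (the parsed summary object).
#' @export
run_workflow <- function(out_dir, seed = 1,
                         guide = "UCCAAACGAGUCUCCGUCG",
                         n_genes = 1000, implant_fraction = 0.1,
                         planted_lfc = -0.3,
                         stages = c("simulate", "scan", "offtarget",
                                    "composite", "pk")) {
  known <- c("simulate", "scan", "offtarget", "composite", "pk")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  summary <- list(seed = seed, guide = guide, stages = stages)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_tsv(x, p)
    manifest <<- c(manifest, p)
  }

  utr_db <- matches <- bg <- NULL
  if ("simulate" %in% stages) {
    utr_db <- sim_utr_database(n_genes = n_genes, implant_fraction = implant_fraction,
                               guide = guide, seed = seed)
    write_fasta(utr_db$utrs, file.path(out_dir, "utrs.fasta"))
    manifest <- c(manifest, file.path(out_dir, "utrs.fasta"))
    summary$n_utrs <- length(utr_db$utrs)
    summary$n_implanted <- length(utr_db$registry)
  }
  if ("scan" %in% stages) {
    if (is.null(utr_db)) stop("stage 'scan' requires 'simulate'", call. = FALSE)
    seeds <- extract_seeds(guide)
    matches <- scan_utr_matches(seeds, utr_db$utrs)
    emit(seeds, "seeds.tsv")
    emit(matches, "seed_matches.tsv")
    summary$n_6mer_hits <- sum(matches$hit[matches$class == "6mer"])
  }
  if ("offtarget" %in% stages) {
    if (is.null(matches)) stop("stage 'offtarget' requires 'scan'", call. = FALSE)
    bg <- build_simulated_background(utr_db$utrs, exclude = extract_seeds(guide),
                                     seed = seed + 1L)
    hit6 <- matches$gene_id[matches$class == "6mer" & matches$hit]
    expt <- sim_expression_experiment(n_genes = length(utr_db$utrs),
                                      planted = hit6, lfc = planted_lfc,
                                      seed = seed + 2L)
    de <- welch_de(expt$counts, expt$group)
    keep <- filter_low_expression(log2cpm_matrix(expt$counts),
                                  threshold = -3)
    fc <- stats::setNames(de$log2fc, de$gene_id)[keep]
    prof <- seed_offtarget_profile(fc, matches, bg$genes)
    emit(de, "de_table.tsv")
    emit(prof, "offtarget_profile.tsv")
    summary$offtarget <- prof
  }
  if ("composite" %in% stages) {
    ct <- sim_ct_table(seed = seed + 3L)
    comp <- fshd_composite(ct, c("MBD3L2", "ZSCAN4", "LEUTX", "KHDC1L"),
                           c("AHSA1", "RPL27"))
    emit(ct, "ct_table.tsv")
    emit(comp$per_well, "composite_per_well.tsv")
    emit(comp$summary, "composite_summary.tsv")
    summary$composite <- comp$summary
  }
  if ("pk" %in% stages) {
    series <- sim_conc_time(seed = seed + 4L)
    hl <- fit_halflife_lnlinear(series$time, series$conc)
    dr <- sim_dose_response(noise_sd = 2, seed = seed + 5L)
    fit <- fit_log_inhibitor_response_3p(dr$conc, dr$response)
    emit(series, "conc_time.tsv")
    emit(dr, "dose_response.tsv")
    summary$pk <- list(t_half_days = hl$t_half, ec50_nm = fit$ec50,
                       emax = fit$emax)
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, summary_path)
  list(status = 0L, manifest = manifest, summary = summary)
}
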