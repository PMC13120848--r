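#' Extract the four seed sequences from an siRNA guide strand
#'
#' The microRNA-like off-target potential of an siRNA is driven by its seed
#' region, bases 1-8 from the 5' end of the guide strand. Four seed
#' length-classes are read from that 8-nt prefix: the 8mer (bases 1-8), two
#' 7mers (bases 1-7 and 2-8), and a 6mer whose window is configurable.
#'
#' @param guide Guide-strand sequence, 5' to 3', over the RNA alphabet
#'   \{A,C,G,U\}. Length must be at least 8 nt (guides are typically 19-23 nt).
#' @param six_mer Window convention for the 6mer seed within bases 1-8:
#'   `"2_7"` (default, the canonical miRNA seed), `"1_6"`, or `"3_8"`.
#' @return A data.frame with columns `class` (`"6mer"`, `"7mer_a"`, `"7mer_b"`,
#'   `"8mer"`), `start`, `end` (1-based guide positions) and `seed` (RNA
#'   string). Exactly four rows, every seed a substring of bases 1-8.
#' @examples
#' extract_seeds("UCCAAACGAGUCUCCGUCG")
#' @export
extract_seeds <- function(guide, six_mer = c("2_7", "1_6", "3_8")) {
  six_mer <- match.arg(six_mer)
  stopifnot(is.character(guide), length(guide) == 1L)
  guide <- toupper(guide)
  stop_if_not_rna(guide)
  if (nchar(guide) < 8L) {
    stop("guide strand must be at least 8 nt to define its seed region, got ",
         nchar(guide), " nt", call. = FALSE)
  }
  six <- switch(six_mer, "2_7" = c(2L, 7L), "1_6" = c(1L, 6L), "3_8" = c(3L, 8L))
  windows <- data.frame(
    class = c("6mer", "7mer_a", "7mer_b", "8mer"),
    start = c(six[1], 1L, 2L, 1L),
    end   = c(six[2], 7L, 8L, 8L),
    stringsAsFactors = FALSE
  )
  windows$seed <- substr(rep(guide, nrow(windows)), windows$start, windows$end)
  windows
}

#' Count seed-match target sites in 3'UTR sequences
#'
#' A seed match at a UTR position means the (sense-strand, 5' to 3') UTR
#' carries the DNA reverse complement of the RNA seed. Overlapping occurrences
#' are counted individually; the per-gene `hit` flag is `count > 0`. Positions
#' containing `N` never participate in a match.
#'
#' @param seeds Seed table as returned by [extract_seeds()] (columns `class`,
#'   `seed`), or any data.frame with those columns.
#' @param utrs Named character vector or `DNAStringSet` of 3'UTR sequences
#'   (DNA alphabet, names are gene ids).
#' @return A data.frame with one row per (gene, seed class): `gene_id`,
#'   `class`, `count`, `hit`.
#' @examples
#' seeds <- extract_seeds("UCCAAACGAGUCUCCGUCG")
#' scan_utr_matches(seeds, c(geneA = "AAGTTTGGAA", geneB = "ACGTACGT"))
#' @export
scan_utr_matches <- function(seeds, utrs) {
  stopifnot(is.data.frame(seeds), all(c("class", "seed") %in% names(seeds)))
  utrs <- as_utr_vector(utrs)
  subject <- Biostrings::DNAStringSet(utrs)
  out <- lapply(seq_len(nrow(seeds)), function(i) {
    site <- seed_site_dna(seeds$seed[i])
    # fixed = TRUE: exact letter match only, so N never matches.
    counts <- Biostrings::vcountPattern(site, subject, fixed = TRUE)
    data.frame(gene_id = names(utrs), class = seeds$class[i],
               count = counts, hit = counts > 0L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$class), , drop = FALSE]
}

#' Build the simulated-siRNA background gene set
#'
#' Draws random guide strands (i.i.d. uniform nucleotides) and returns the
#' union of genes whose 3'UTR carries at least one 6mer seed match for any of
#' them. This defines the background fold-change distribution against which
#' the test siRNA's seed-matched genes are compared. Simulated guides whose
#' 6mer seed equals any seed of the test siRNA are rejected and redrawn, so
#' the background is not contaminated by true seed targets.
#'
#' @param utrs Named character vector or `DNAStringSet` of 3'UTRs.
#' @param exclude Seed table of the test siRNA ([extract_seeds()] output);
#'   simulated guides whose 6mer equals any `exclude$seed` entry are redrawn.
#'   May be `NULL` to disable the exclusion rule.
#' @param n_simulated Number of simulated siRNAs (default 10).
#' @param guide_length Simulated guide length in nt (default 19).
#' @param seed Integer RNG seed (default 1020); the result is a pure function
#'   of the arguments.
#' @param six_mer 6mer window convention, as in [extract_seeds()].
#' @return List with `genes` (character vector of background gene ids) and
#'   `guides` (the simulated guide sequences actually used).
#' @export
build_simulated_background <- function(utrs, exclude = NULL, n_simulated = 10,
                                       guide_length = 19, seed = 1020,
                                       six_mer = "2_7") {
  utrs <- as_utr_vector(utrs)
  if (n_simulated < 1) stop("n_simulated must be >= 1", call. = FALSE)
  excl_seeds <- if (is.null(exclude)) character(0) else exclude$seed
  withr::with_seed(seed, {
    guides <- character(n_simulated)
    hit_genes <- character(0)
    for (i in seq_len(n_simulated)) {
      repeat {
        g <- paste(sample(c("A", "C", "G", "U"), guide_length, replace = TRUE),
                   collapse = "")
        s6 <- extract_seeds(g, six_mer = six_mer)
        s6 <- s6$seed[s6$class == "6mer"]
        if (!s6 %in% excl_seeds) break
      }
      guides[i] <- g
      tab <- scan_utr_matches(extract_seeds(g, six_mer = six_mer), utrs)
      hit_genes <- union(hit_genes, tab$gene_id[tab$class == "6mer" & tab$hit])
    }
    list(genes = sort(hit_genes), guides = guides)
  })
}

#' Hamming distance between two equal-length sequences
#'
#' Position-by-position mismatch count, e.g. between the human and cynomolgus
#' monkey siRNA target sites (which differ at a single nucleotide).
#'
#' @param a,b Character scalars of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming_distance("CGACGGAGACTCGTTTGGA", "CGAAGGAGACTCGTTTGGA")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
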