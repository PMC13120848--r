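# Internal helpers shared across modules.

# Geometric mean; x must be positive.
geomean <- function(x) exp(mean(log(x)))

# DNA reverse complement of a character vector of sequences.
rc_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Convert an RNA seed (ACGU) to the DNA site it pairs with in a sense-strand
# 3'UTR: U -> T, then reverse complement.
seed_site_dna <- function(seed_rna) {
  rc_dna(chartr("U", "T", seed_rna))
}

stop_if_not_rna <- function(sequence, what = "guide") {
  bad <- grepl("[^ACGU]", sequence)
  if (any(bad)) {
    stop(sprintf("%s sequence contains characters outside {A,C,G,U}: %s",
                 what, paste(unique(unlist(strsplit(
                   gsub("[ACGU]", "", sequence[bad]), ""))), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce UTR input (named character vector or DNAStringSet) to a named,
# upper-case character vector. Names are gene ids and must be present.
as_utr_vector <- function(utrs) {
  if (methods::is(utrs, "XStringSet")) {
    utrs <- as.character(utrs)
  }
  if (!is.character(utrs) || length(utrs) == 0L) {
    stop("utrs must be a non-empty named character vector or DNAStringSet",
         call. = FALSE)
  }
  if (is.null(names(utrs)) || any(!nzchar(names(utrs)))) {
    stop("every UTR record needs a gene id (names attribute)", call. = FALSE)
  }
  toupper(utrs)
}
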