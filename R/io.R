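# Readers/writers. Delimited files are tab-separated with a header row;
# FASTA is read with arbitrary line wrapping and written 60 columns wide.

#' Read guide strands from FASTA
#'
#' Records are upper-cased and T is converted to U, so guides may be stored in
#' either DNA or RNA letters; anything else raises an alphabet error naming
#' the record.
#'
#' @param path FASTA file of guide-strand sequences (record id = guide id).
#' @return Named character vector of RNA guide sequences.
#' @export
read_guides_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- chartr("T", "U", toupper(as.character(x)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (i in seq_along(seqs)) {
    if (grepl("[^ACGU]", seqs[i])) {
      stop("invalid guide alphabet in ", path, ", record '", names(seqs)[i],
           "'", call. = FALSE)
    }
  }
  seqs
}

#' Read 3'UTR sequences from FASTA
#'
#' @param path FASTA file of sense-strand DNA 3'UTRs (record id = gene id).
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_utrs_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(what, " ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a differential-expression table
#'
#' Requires columns `gene_id`, `log2fc`, `p_value`, `fdr`; `avg_log2cpm` is
#' optional.
#'
#' @param path Tab-separated file with a header row.
#' @return Data.frame.
#' @export
read_de_table <- function(path) {
  read_tsv_checked(path, c("gene_id", "log2fc", "p_value", "fdr"), "DE table")
}

#' Read a Ct table
#'
#' Requires `sample` and `condition` columns; remaining columns are genes.
#'
#' @param path Tab-separated file with a header row.
#' @return Data.frame.
#' @export
read_ct_table <- function(path) {
  read_tsv_checked(path, c("sample", "condition"), "Ct table")
}

#' Write a delimited table
#'
#' Tab-separated, header row, no quoting or row names — re-readable by the
#' `read_*` functions.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
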