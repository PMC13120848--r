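# Independent brute-force oracles, deliberately naive.

# Count every k-window of `utr` equal to `site` (overlaps included).
brute_count_sites <- function(site, utr) {
  k <- nchar(site)
  if (nchar(utr) < k) return(0L)
  sum(vapply(seq_len(nchar(utr) - k + 1L),
             function(i) substr(utr, i, i + k - 1L) == site, logical(1)))
}

# AUC by exhaustive pair enumeration.
brute_auc <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) {
    s <- s + (xi < yj) + 0.5 * (xi == yj)
  }
  s / (length(x) * length(y))
}

# KS D by evaluating both ECDFs at every sample point.
brute_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Hand-written BH step-up.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Position-by-position mismatch loop.
brute_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) if (av[i] != bv[i]) n <- n + 1L
  n
}

# Random RNA guide of length n.
random_guide <- function(n = 19) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random DNA UTR set.
random_utrs <- function(n, len = 60) {
  u <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(u) <- paste0("g", seq_len(n))
  u
}

# The guide complementary to the printed human siDUX4.6 target site.
SIDUX4_GUIDE <- "UCCAAACGAGUCUCCGUCG"
HUMAN_TARGET_SITE <- "CGACGGAGACTCGTTTGGA"
CYNO_TARGET_SITE <- "CGAAGGAGACTCGTTTGGA"
MUTATED_TARGET_SITE <- "ACAACAGACTTTAATGTAA"
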