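# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings) so they can stand as references.

# Quadratic Hamming scanner: occurrences of `pattern` in `subject` with at
# most `max_mismatch` substitutions; overlapping starts all counted;
# case-insensitive; any pairing with a non-ACGT subject letter mismatches.
brute_count <- function(pattern, subject, max_mismatch = 0) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  lp <- length(p); ls <- length(s)
  if (lp > ls) return(0L)
  hits <- 0L
  for (i in seq_len(ls - lp + 1L)) {
    w <- s[i:(i + lp - 1L)]
    mm <- sum(w != p | !w %in% c("A", "C", "G", "T"))
    if (mm <= max_mismatch) hits <- hits + 1L
  }
  hits
}

# O(mn) direct sup of the ECDF difference over all pooled sample points.
brute_ks_d <- function(x, y, alternative) {
  pts <- c(x, y)
  diffs <- vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))
  switch(alternative,
         "match-down" = max(diffs),
         "match-up" = max(-diffs),
         "two-sided" = max(abs(diffs)))
}

# Plain-character reverse complement (DNA).
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Extract a spliced feature by hand: substring each interval from the
# chromosome string in genomic order, concatenate, reverse-complement the
# whole thing for minus-strand features.
brute_extract <- function(chrom_seq, starts, ends, strand) {
  o <- order(starts)
  s <- paste(mapply(function(a, b) substr(chrom_seq, a, b),
                    starts[o], ends[o]),
             collapse = "")
  if (strand == "-") revcomp_chr(s) else s
}

rand_dna_chr <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
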