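# shared helpers: the bundled reference is loaded once per test run
REF <- mito_reference()

# constant-quality string
qstr <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

# a reads data.frame from raw sequences
reads_df <- function(seqs, q = 40, ids = sprintf("t%03d", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs,
             qual = vapply(nchar(seqs), function(n) qstr(q, n), ""),
             stringsAsFactors = FALSE)
}

# brute-force homopolymer oracle on the circular sequence: rotate the string
# so pos sits mid-string, then scan linearly
homopolymer_oracle <- function(ref, pos) {
  L <- ref$length
  rot <- paste0(substring(ref$sequence, pos, L),
                substring(ref$sequence, 1, pos - 1))
  chars <- strsplit(rot, "")[[1L]]
  base <- chars[1L]
  len <- 1L
  i <- 2L
  while (chars[i] == base) { len <- len + 1L; i <- i + 1L }
  i <- L
  while (chars[i] == base) { len <- len + 1L; i <- i - 1L }
  list(length = len, base = base)
}

# brute-force per-read pileup recount: tally coverage and non-reference
# alleles directly from aligned read sequences
pileup_oracle <- function(alignment, ref) {
  L <- ref$length
  cov <- matrix(0L, nrow = L, ncol = 2, dimnames = list(NULL, c("plus", "minus")))
  alt <- list()
  al <- alignment$aligned
  for (i in seq_len(nrow(al))) {
    bases <- strsplit(al$seq[i], "")[[1L]]
    # only ungapped reads enter the oracle (width == read length)
    stopifnot(al$width[i] == length(bases))
    pos <- ((al$start[i] + seq_along(bases) - 2L) %% L) + 1L
    cov[pos, al$strand[i]] <- cov[pos, al$strand[i]] + 1L
    refb <- strsplit(ref_segment(ref, al$start[i], length(bases)), "")[[1L]]
    mm <- which(bases != refb)
    for (j in mm) {
      key <- paste(pos[j], bases[j], al$strand[i])
      alt[[key]] <- (if (is.null(alt[[key]])) 0L else alt[[key]]) + 1L
    }
  }
  list(cov = cov, alt = alt)
}
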