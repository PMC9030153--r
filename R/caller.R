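# Variant-calling pipeline: read quality filtering, circular-aware
# seed-and-extend mapping with indel rescue, clonal-read collapsing,
# nuclear-contamination estimation, strand-split pileups, and threshold-based
# calling with strand-skew and blacklist exclusion.

#' Filter reads on runs of low-quality bases
#'
#' A read is discarded if and only if it contains a run of *more than*
#' `run_length` consecutive bases each with phred quality below
#' `q_threshold`; all other reads are retained unmodified (a run of exactly
#' `run_length` low-quality bases is kept).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (phred+33).
#' @param q_threshold Phred threshold (default 20).
#' @param run_length Maximum tolerated run of sub-threshold bases (default 10).
#' @return list with `retained` and `discarded` data.frames.
#' @export
filter_read_quality <- function(reads, q_threshold = 20, run_length = 10) {
  if (any(!nzchar(reads$qual)) || any(nchar(reads$qual) != nchar(reads$seq)))
    stop("malformed quality strings")
  # bases with Q < q_threshold are the characters below chr(33 + q_threshold)
  hi <- 33L + q_threshold - 1L
  if (hi > 126L) hi <- 126L
  pattern <- sprintf("[\\x21-\\x%02X]{%d,}", hi, run_length + 1L)
  bad <- grepl(pattern, reads$qual, perl = TRUE)
  list(retained = reads[!bad, , drop = FALSE],
       discarded = reads[bad, , drop = FALSE])
}

# k-mer index over a sequence; value = first occurrence position
build_kmer_index <- function(sequence, k) {
  n <- nchar(sequence) - k + 1L
  kmers <- substring(sequence, seq_len(n), seq_len(n) + k - 1L)
  list(kmers = kmers, k = k)
}

# first candidate start per read from seeds at the given read offsets
seed_candidates <- function(seqs, index, offsets) {
  cand <- rep(NA_integer_, length(seqs))
  for (off in offsets) {
    todo <- which(is.na(cand) & nchar(seqs) >= off + index$k)
    if (!length(todo)) next
    seeds <- substring(seqs[todo], off + 1L, off + index$k)
    hit <- match(seeds, index$kmers)
    cand[todo] <- hit - off
  }
  cand
}

# mismatch details between equal-length string vectors: counts, positions and
# the read bases at each mismatch
mismatch_details <- function(reads, refs) {
  n <- length(reads)
  out <- list(n = integer(n), pos = vector("list", n),
              base = vector("list", n))
  if (!n) return(out)
  lens <- nchar(reads)
  for (len in unique(lens)) {
    idx <- which(lens == len)
    a <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE),
                       use.names = FALSE), nrow = len)
    b <- matrix(unlist(strsplit(refs[idx], "", fixed = TRUE),
                       use.names = FALSE), nrow = len)
    neq <- a != b
    out$n[idx] <- colSums(neq)
    w <- which(neq, arr.ind = TRUE)
    fac <- factor(w[, 2L], levels = seq_along(idx))
    out$pos[idx] <- split(w[, 1L], fac)
    out$base[idx] <- split(a[w], fac)
  }
  out
}

rc_chr <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split-read rescue of a read whose ungapped extension failed: allows one
# short internal indel (1-2 bases) plus up to max_mismatch substitutions, by
# minimizing prefix + shifted-suffix mismatch counts over all split points.
# Within homopolymers the 3'-most split is chosen, matching the notation in
# which an inserted base is anchored at the run's 3' end (C5899CC).
rescue_alignment <- function(read, doubled, cand, L, max_mismatch,
                             max_indel = 2L) {
  len <- nchar(read)
  if (cand + len + max_indel > nchar(doubled)) return(NULL)
  r <- strsplit(read, "", fixed = TRUE)[[1L]]
  w <- strsplit(substring(doubled, cand, cand + len + max_indel - 1L),
                "", fixed = TRUE)[[1L]]
  p0 <- cumsum(r != w[seq_len(len)])
  pre <- function(s) if (s > 0L) p0[s] else 0L
  best <- NULL
  for (g in seq_len(max_indel)) {
    # insertion of g read bases after split s: read[j+g] aligns ref[j]
    n_tail <- len - g
    tail_mm <- r[(g + 1L):len] != w[seq_len(n_tail)]
    suf <- rev(cumsum(rev(tail_mm)))
    ss <- 1L:(n_tail - 1L)
    costs <- vapply(ss, function(s) pre(s) + suf[s + 1L], 0L)
    mn <- min(costs)
    if (mn <= max_mismatch && (is.null(best) || mn < best$cost))
      best <- list(type = "ins", g = g, s = ss[max(which(costs == mn))],
                   cost = mn)
    # deletion of g reference bases after split s: read[j] aligns ref[j+g]
    tail_mm_d <- r != w[seq_len(len) + g]
    sufd <- rev(cumsum(rev(tail_mm_d)))
    ssd <- 1L:(len - 1L)
    costs_d <- vapply(ssd, function(s) pre(s) + sufd[s + 1L], 0L)
    mnd <- min(costs_d)
    if (mnd <= max_mismatch && (is.null(best) || mnd < best$cost))
      best <- list(type = "del", g = g, s = ssd[max(which(costs_d == mnd))],
                   cost = mnd)
  }
  if (is.null(best)) return(NULL)
  s <- best$s; g <- best$g
  if (best$type == "ins") {
    pre_idx <- which(r[seq_len(s)] != w[seq_len(s)])
    tail_j <- (s + 1L):(len - g)
    tail_idx <- tail_j[r[tail_j + g] != w[tail_j]]
    mism <- data.frame(
      pos = wrap_pos(cand + c(pre_idx, tail_idx) - 1L, L),
      base = c(r[pre_idx], r[tail_idx + g]), stringsAsFactors = FALSE)
    ins <- data.frame(anchor = wrap_pos(cand + s - 1L, L),
                      base = paste(r[(s + 1L):(s + g)], collapse = ""),
                      stringsAsFactors = FALSE)
    list(start = wrap_pos(cand, L), width = len - g, mismatches = mism,
         insertions = ins, indels = g, cost = best$cost)
  } else {
    pre_idx <- which(r[seq_len(s)] != w[seq_len(s)])
    tail_j <- (s + 1L):len
    tail_idx <- tail_j[r[tail_j] != w[tail_j + g]]
    mism <- data.frame(
      pos = wrap_pos(cand + c(pre_idx, tail_idx + g) - 1L, L),
      base = c(r[pre_idx], r[tail_idx]), stringsAsFactors = FALSE)
    list(start = wrap_pos(cand, L), width = len + g, mismatches = mism,
         insertions = NULL, indels = g, cost = best$cost)
  }
}

#' Map reads to the circular mitochondrial genome
#'
#' Exact-or-near-exact seed-and-extend mapping over the doubled circular
#' sequence, so reads spanning the origin map without special handling. Each
#' read is assigned source `mito` (with position and strand), `repeat-decoy`
#' (it matches the nuclear repeat library), or `unmapped`; nothing is dropped
#' silently. Reads whose ungapped extension fails are rescued by gapped
#' alignment (up to one short indel), which is how single-base insertion
#' carriers are recovered.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param ref A `mito_reference`.
#' @param decoys Optional named character vector of repeat decoy sequences.
#' @param max_mismatch Maximum mismatches tolerated in ungapped extension.
#' @param seed_length Seed k-mer length.
#' @return list of class `mito_alignment`: `aligned` (data.frame `id`,
#'   `start`, `strand`, `width`, `mm`, `seq`, `qual` — `seq` in L-strand
#'   orientation), `mismatches` (`id`, `pos`, `base`), `insertions` (`id`,
#'   `anchor`, `bases`), `sources` (per input read: mito / repeat-decoy /
#'   unmapped), and `ref_length`.
#' @export
map_circular <- function(reads, ref, decoys = NULL, max_mismatch = 2,
                         seed_length = 16) {
  if (anyDuplicated(reads$id)) stop("read ids must be unique")
  L <- ref$length
  rl_max <- max(nchar(reads$seq), 0L)
  doubled <- paste0(ref$sequence, substring(ref$sequence, 1L, rl_max + 50L))
  index <- build_kmer_index(doubled, seed_length)
  n <- nrow(reads)
  res_start <- rep(NA_integer_, n)
  res_strand <- rep(NA_character_, n)
  res_mm <- rep(NA_integer_, n)
  res_seq <- reads$seq          # L-strand-oriented sequence once mapped
  res_width <- nchar(reads$seq)
  source <- rep("unmapped", n)
  mism_rows <- list(); ins_rows <- list()

  try_orientation <- function(todo, seqs) {
    # returns list(mapped_idx(local), start, mm, details) for ungapped hits
    cand <- seed_candidates(seqs, index, c(0L, seed_length, 2L * seed_length))
    ok <- which(!is.na(cand) & cand >= 1L)
    if (!length(ok)) return(list(hit = integer(), cand = cand))
    expect <- substring(doubled, cand[ok], cand[ok] + nchar(seqs[ok]) - 1L)
    exact <- seqs[ok] == expect
    det <- mismatch_details(seqs[ok][!exact], expect[!exact])
    near <- det$n <= max_mismatch
    hit_local <- c(ok[exact], ok[!exact][near])
    list(hit = hit_local, cand = cand,
         start = cand[hit_local],
         mm = c(rep(0L, sum(exact)), det$n[near]),
         mm_pos = c(rep(list(integer()), sum(exact)), det$pos[near]),
         mm_base = c(rep(list(character()), sum(exact)), det$base[near]))
  }

  record_hits <- function(todo, o, strand, seqs) {
    if (!length(o$hit)) return(invisible())
    gi <- todo[o$hit]
    res_start[gi] <<- wrap_pos(o$start, L)
    res_strand[gi] <<- strand
    res_mm[gi] <<- o$mm
    res_seq[gi] <<- seqs[o$hit]
    source[gi] <<- "mito"
    has <- which(o$mm > 0L)
    if (length(has)) {
      lens <- lengths(o$mm_pos[has])
      mism_rows[[length(mism_rows) + 1L]] <<- data.frame(
        id = rep(reads$id[todo[o$hit[has]]], lens),
        pos = wrap_pos(rep(o$start[has], lens) + unlist(o$mm_pos[has]) - 1L, L),
        base = unlist(o$mm_base[has]), stringsAsFactors = FALSE)
    }
  }

  todo <- seq_len(n)
  o_fwd <- try_orientation(todo, reads$seq[todo])
  record_hits(todo, o_fwd, "plus", reads$seq[todo])
  cand_fwd <- o_fwd$cand

  todo2 <- which(source == "unmapped")
  rc <- rc_chr(reads$seq[todo2])
  o_rev <- if (length(todo2)) try_orientation(todo2, rc) else
    list(hit = integer(), cand = integer())
  record_hits(todo2, o_rev, "minus", rc)
  cand_rev <- rep(NA_integer_, n)
  if (length(todo2)) cand_rev[todo2] <- o_rev$cand

  # gapped rescue for reads with a candidate but failed extension
  todo3 <- which(source == "unmapped")
  for (i in todo3) {
    cand <- cand_fwd[i]; strand <- "plus"; sq <- reads$seq[i]
    if (is.na(cand) || cand < 1L) {
      cand <- cand_rev[i]; strand <- "minus"
      sq <- if (!is.na(cand)) rc_chr(reads$seq[i]) else sq
    }
    if (is.na(cand) || cand < 1L) next
    # the seed that produced the candidate may sit downstream of the indel,
    # in which case the true alignment start is shifted by the indel length
    r <- NULL
    for (shift in c(0L, 1L, -1L, 2L, -2L)) {
      if (cand + shift < 1L) next
      r2 <- rescue_alignment(sq, doubled, cand + shift, L, max_mismatch)
      if (!is.null(r2) && (is.null(r) || r2$cost < r$cost)) r <- r2
    }
    if (is.null(r)) next
    res_start[i] <- r$start
    res_strand[i] <- strand
    res_mm[i] <- nrow(r$mismatches)
    res_seq[i] <- sq
    res_width[i] <- r$width
    source[i] <- "mito"
    if (nrow(r$mismatches))
      mism_rows[[length(mism_rows) + 1L]] <- cbind(
        data.frame(id = reads$id[i], stringsAsFactors = FALSE), r$mismatches)
    if (!is.null(r$insertions))
      ins_rows[[length(ins_rows) + 1L]] <- data.frame(
        id = reads$id[i], anchor = r$insertions$anchor,
        bases = r$insertions$base, stringsAsFactors = FALSE)
  }

  # repeat-decoy assignment for whatever is still unmapped
  if (!is.null(decoys) && length(decoys)) {
    dseq <- paste(decoys, collapse = strrep("N", 40L))
    dindex <- build_kmer_index(dseq, seed_length)
    todo4 <- which(source == "unmapped")
    for (seqs_or in list(list(s = reads$seq[todo4], idx = todo4),
                         list(s = rc_chr(reads$seq[todo4]), idx = todo4))) {
      left <- seqs_or$idx[source[seqs_or$idx] == "unmapped"]
      if (!length(left)) next
      sq <- seqs_or$s[match(left, seqs_or$idx)]
      cand <- seed_candidates(sq, dindex, c(0L, seed_length))
      ok <- which(!is.na(cand) & cand >= 1L)
      if (!length(ok)) next
      expect <- substring(dseq, cand[ok], cand[ok] + nchar(sq[ok]) - 1L)
      det <- mismatch_details(sq[ok], expect)
      source[left[ok][det$n <= max_mismatch]] <- "repeat-decoy"
    }
  }

  aligned <- data.frame(id = reads$id, start = res_start, strand = res_strand,
                        width = res_width, mm = res_mm, seq = res_seq,
                        qual = reads$qual, stringsAsFactors = FALSE)
  aligned <- aligned[source == "mito", , drop = FALSE]
  structure(list(
    aligned = aligned,
    mismatches = if (length(mism_rows)) do.call(rbind, mism_rows) else
      data.frame(id = character(), pos = integer(), base = character()),
    insertions = if (length(ins_rows)) do.call(rbind, ins_rows) else
      data.frame(id = character(), anchor = integer(), bases = character()),
    sources = data.frame(id = reads$id, source = source,
                         stringsAsFactors = FALSE),
    ref_length = L), class = "mito_alignment")
}

#' Collapse clonal reads
#'
#' Identical reads (same mapped start, strand and sequence) are clonal copies
#' of one original molecule fragment and are considered only once toward
#' variant calling, irrespective of the number of copies. Exactly one
#' representative per clonal key is kept; multiplicities are recorded.
#'
#' @param alignment A `mito_alignment`.
#' @return The alignment restricted to non-clonal representatives, with a
#'   `multiplicity` data.frame (`key`, `id` of representative, `count`)
#'   attached as element `multiplicity`.
#' @export
collapse_clonal <- function(alignment) {
  al <- alignment$aligned
  key <- paste(al$start, al$strand, al$seq, sep = "|")
  first <- !duplicated(key)
  reps <- al$id[first]
  counts <- as.vector(table(factor(key, levels = unique(key))))
  alignment$aligned <- al[first, , drop = FALSE]
  keep <- alignment$aligned$id
  alignment$mismatches <-
    alignment$mismatches[alignment$mismatches$id %in% keep, , drop = FALSE]
  alignment$insertions <-
    alignment$insertions[alignment$insertions$id %in% keep, , drop = FALSE]
  alignment$multiplicity <- data.frame(key = unique(key), id = reps,
                                       count = counts,
                                       stringsAsFactors = FALSE)
  alignment
}

#' Estimate nuclear DNA contamination from repeat-mapped reads
#'
#' Repeat elements (LINEs/SINEs) occur only in nuclear DNA, so the fraction
#' of reads mapping to the repeat library, scaled by the genomic fraction the
#' library represents, estimates the nuclear fraction of the sample:
#' `(repeat reads / repeat_genomic_fraction) / total reads`, clamped to
#' \[0, 1\].
#'
#' @param alignment A `mito_alignment` (or a list with a `sources` element).
#' @param repeat_genomic_fraction Fraction of the nuclear genome represented
#'   by the repeat library, in (0, 1\].
#' @return list with `repeat_reads`, `total_reads`, `nuclear_fraction`,
#'   `calibration` (the genomic fraction used).
#' @export
estimate_contamination <- function(alignment, repeat_genomic_fraction = 0.3) {
  if (repeat_genomic_fraction <= 0 || repeat_genomic_fraction > 1)
    stop("repeat_genomic_fraction must be in (0, 1]")
  total <- nrow(alignment$sources)
  if (total == 0L) stop("no reads")
  n_rep <- sum(alignment$sources$source == "repeat-decoy")
  est <- min(1, max(0, (n_rep / repeat_genomic_fraction) / total))
  list(repeat_reads = n_rep, total_reads = total, nuclear_fraction = est,
       calibration = repeat_genomic_fraction)
}

#' Build a strand-split pileup from non-clonal aligned reads
#'
#' Counts, at every reference position, the non-clonal read coverage per
#' strand and every non-reference allele observed (substitution alleles by
#' position, insertion alleles keyed by their anchor position).
#'
#' @param alignment A `mito_alignment`, normally after [collapse_clonal()].
#' @param ref A `mito_reference`.
#' @return list of class `mito_pileup`: `cov_plus`, `cov_minus` (integer
#'   vectors over the genome), `alts` (data.frame `pos`, `allele`, `style`,
#'   `plus`, `minus`), and `ref`.
#' @export
build_pileup <- function(alignment, ref) {
  L <- ref$length
  al <- alignment$aligned
  cov <- function(rows) {
    d <- integer(L + 1L)
    if (nrow(rows)) for (i in seq_len(nrow(rows))) {
      s <- rows$start[i]; e <- s + rows$width[i] - 1L
      if (e <= L) {
        d[s] <- d[s] + 1L; d[e + 1L] <- d[e + 1L] - 1L
      } else {
        d[s] <- d[s] + 1L
        e2 <- e - L
        d[1L] <- d[1L] + 1L; d[e2 + 1L] <- d[e2 + 1L] - 1L
      }
    }
    cumsum(d[seq_len(L)])
  }
  cov_plus <- cov(al[al$strand == "plus", , drop = FALSE])
  cov_minus <- cov(al[al$strand == "minus", , drop = FALSE])

  strand_of <- al$strand[match(alignment$mismatches$id, al$id)]
  alts <- data.frame(pos = integer(), allele = character(),
                     style = character(), plus = integer(), minus = integer(),
                     stringsAsFactors = FALSE)
  mm <- alignment$mismatches
  if (nrow(mm)) {
    tab <- stats::aggregate(
      list(count = rep(1L, nrow(mm))),
      by = list(pos = mm$pos, allele = mm$base, strand = strand_of), sum)
    wide <- stats::reshape(tab, idvar = c("pos", "allele"),
                           timevar = "strand", direction = "wide")
    plus <- wide$count.plus; minus <- wide$count.minus
    if (is.null(plus)) plus <- rep(NA_integer_, nrow(wide))
    if (is.null(minus)) minus <- rep(NA_integer_, nrow(wide))
    alts <- data.frame(pos = wide$pos, allele = wide$allele,
                       style = "substitution",
                       plus = ifelse(is.na(plus), 0L, plus),
                       minus = ifelse(is.na(minus), 0L, minus),
                       stringsAsFactors = FALSE)
  }
  ins <- alignment$insertions
  if (nrow(ins)) {
    strand_i <- al$strand[match(ins$id, al$id)]
    tab <- stats::aggregate(
      list(count = rep(1L, nrow(ins))),
      by = list(pos = ins$anchor, allele = ins$bases, strand = strand_i), sum)
    wide <- stats::reshape(tab, idvar = c("pos", "allele"),
                           timevar = "strand", direction = "wide")
    plus <- wide$count.plus; minus <- wide$count.minus
    if (is.null(plus)) plus <- rep(NA_integer_, nrow(wide))
    if (is.null(minus)) minus <- rep(NA_integer_, nrow(wide))
    alts <- rbind(alts, data.frame(
      pos = wide$pos, allele = wide$allele, style = "insertion",
      plus = ifelse(is.na(plus), 0L, plus),
      minus = ifelse(is.na(minus), 0L, minus), stringsAsFactors = FALSE))
  }
  alts <- alts[order(alts$pos, alts$allele), , drop = FALSE]
  rownames(alts) <- NULL
  structure(list(cov_plus = cov_plus, cov_minus = cov_minus, alts = alts,
                 ref = ref), class = "mito_pileup")
}

#' Call variants from a pileup
#'
#' Every non-reference allele observed is emitted with a filter status. A
#' call PASSes only if it is supported by at least `min_support` non-clonal
#' reads, site coverage is at least `min_coverage`, the minority-strand
#' fraction of supporting reads (the skew) is at least `skew_threshold`
#' (variants carried essentially by one strand are excluded), and the
#' position lies outside the `blacklist` range (a homopolymeric stretch with
#' known artefactual calls). Percent-variant is reported both in the
#' plus-strand convention (`vaf_plus`, supporting plus-strand reads over
#' plus-strand coverage) and over both strands (`vaf_both`).
#'
#' @param pileup A `mito_pileup`.
#' @param min_support Minimum supporting non-clonal reads (default 3).
#' @param min_coverage Minimum non-clonal site coverage (default 10).
#' @param skew_threshold Minimum minority-strand fraction (default 0.1).
#' @param blacklist `c(start, end)` closed positions range, or `NULL`.
#' @return data.frame of class `variant_calls`: `label`, `position`, `ref`,
#'   `alt`, `style`, `coverage`, `support`, `support_plus`, `support_minus`,
#'   `vaf_plus`, `vaf_both`, `skew`, `filter`.
#' @export
call_variants <- function(pileup, min_support = 3, min_coverage = 10,
                          skew_threshold = 0.1, blacklist = c(302L, 315L)) {
  if (min_support <= 0 || min_coverage <= 0)
    stop("thresholds must be positive")
  a <- pileup$alts
  ref <- pileup$ref
  if (nrow(a) == 0L) {
    out <- data.frame(label = character(), position = integer(),
                      ref = character(), alt = character(),
                      style = character(), coverage = integer(),
                      support = integer(), support_plus = integer(),
                      support_minus = integer(), vaf_plus = numeric(),
                      vaf_both = numeric(), skew = numeric(),
                      filter = character(), stringsAsFactors = FALSE)
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  refb <- ref_base(ref, a$pos)
  support <- a$plus + a$minus
  coverage <- pileup$cov_plus[a$pos] + pileup$cov_minus[a$pos]
  skew <- ifelse(support > 0, pmin(a$plus, a$minus) / support, 0)
  vaf_plus <- ifelse(pileup$cov_plus[a$pos] > 0,
                     100 * a$plus / pileup$cov_plus[a$pos], NA_real_)
  vaf_both <- ifelse(coverage > 0, 100 * support / coverage, NA_real_)
  filter <- rep("PASS", nrow(a))
  filter[skew < skew_threshold] <- "strand_skew"
  filter[coverage < min_coverage] <- "low_coverage"
  filter[support < min_support] <- "low_support"
  if (!is.null(blacklist))
    filter[a$pos >= blacklist[1L] & a$pos <= blacklist[2L]] <- "blacklist"
  label <- ifelse(a$style == "substitution",
                  paste0(refb, a$pos, a$allele),
                  paste0(refb, a$pos, refb, a$allele))
  alt <- ifelse(a$style == "substitution", a$allele,
                paste0(refb, a$allele))
  out <- data.frame(label = label, position = a$pos, ref = refb, alt = alt,
                    style = a$style, coverage = coverage, support = support,
                    support_plus = a$plus, support_minus = a$minus,
                    vaf_plus = vaf_plus, vaf_both = vaf_both, skew = skew,
                    filter = filter, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Probability of coincident sequencing errors
#'
#' The chance that `n_reads` independent reads all show the same erroneous
#' variant at one site when the per-base error probability is
#' `per_base_error`: simply `per_base_error ^ n_reads`. At the Q30 error rate
#' of 1e-3, two coincident errors occur about one time in a million and three
#' about one time in a billion, the rationale for requiring at least three
#' non-clonal supporting reads.
#'
#' @param per_base_error Per-base error probability in (0, 1).
#' @param n_reads Number of independent reads (>= 1).
#' @return The coincidence probability.
#' @export
coincident_error_probability <- function(per_base_error, n_reads) {
  if (any(per_base_error <= 0) || any(per_base_error >= 1))
    stop("per_base_error must be in (0, 1)")
  if (any(n_reads < 1)) stop("n_reads must be >= 1")
  per_base_error^n_reads
}

#' Run the full calling pipeline on raw reads
#'
#' Quality filtering, circular mapping, clonal collapsing, contamination
#' estimation, pileup and variant calling in one call.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (e.g. from [read_fastq()]
#'   or `simulate_reads()$reads`).
#' @param ref A `mito_reference`.
#' @param decoys Optional repeat decoy library.
#' @param repeat_genomic_fraction Calibration for [estimate_contamination()].
#' @param ... Passed to [call_variants()].
#' @return list with `calls`, `pileup`, `alignment` (collapsed),
#'   `contamination`, `n_input`, `n_quality_failed`.
#' @export
call_pipeline <- function(reads, ref, decoys = NULL,
                          repeat_genomic_fraction = 0.3, ...) {
  fq <- filter_read_quality(reads)
  alignment <- map_circular(fq$retained, ref, decoys = decoys)
  contamination <- estimate_contamination(alignment, repeat_genomic_fraction)
  collapsed <- collapse_clonal(alignment)
  pileup <- build_pileup(collapsed, ref)
  calls <- call_variants(pileup, ...)
  list(calls = calls, pileup = pileup, alignment = collapsed,
       contamination = contamination, n_input = nrow(reads),
       n_quality_failed = nrow(fq$discarded))
}

#' Write variant calls as VCFv4.2
#'
#' Writes a minimal single-contig VCF with INFO fields DP (non-clonal
#' coverage), SUP (supporting non-clonal reads), VAF_PLUS and VAF_BOTH
#' (percent-variant), SKEW (minority-strand fraction), and the filter status
#' in FILTER. Insertions use the anchor-base convention.
#'
#' @param calls A `variant_calls` data.frame.
#' @param ref A `mito_reference` (for the contig header line).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(calls, ref, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Non-clonal coverage\">",
    "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Supporting non-clonal reads\">",
    "##INFO=<ID=VAF_PLUS,Number=1,Type=Float,Description=\"Percent variant, plus-strand convention\">",
    "##INFO=<ID=VAF_BOTH,Number=1,Type=Float,Description=\"Percent variant, both strands\">",
    "##INFO=<ID=SKEW,Number=1,Type=Float,Description=\"Minority-strand fraction of support\">",
    "##FILTER=<ID=low_support,Description=\"Fewer than 3 non-clonal supporting reads\">",
    "##FILTER=<ID=low_coverage,Description=\"Site coverage below 10\">",
    "##FILTER=<ID=strand_skew,Description=\"Support essentially on one strand\">",
    "##FILTER=<ID=blacklist,Description=\"Within the excluded homopolymeric region\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\t%s\tDP=%d;SUP=%d;VAF_PLUS=%.4g;VAF_BOTH=%.4g;SKEW=%.4g",
    ref$name, calls$position, calls$label, calls$ref, calls$alt, calls$filter,
    calls$coverage, calls$support, calls$vaf_plus, calls$vaf_both, calls$skew)
  writeLines(c(hdr, body), path)
  invisible(path)
}
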