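# Synthetic-data generators: molecule populations under an exonuclease V
# digestion model, FASTQ read simulation with truth tables, read-count tables
# for published-table style reanalysis, and densitometry lane profiles.

#' Simulation configuration
#'
#' @param mean_depth Target read depth per position of the mitochondrial
#'   genome (before any dilution by nuclear molecules).
#' @param read_length Maximum read length in bases.
#' @param read_length_jitter Reads are emitted with lengths uniform in
#'   `[read_length - read_length_jitter, read_length]`, emulating variable
#'   insert sizes and adapter/quality trimming. This is what makes the
#'   identical-read clonal rule meaningful: with it, byte-identical reads are
#'   (near-)always true clonal duplicates rather than coincident fragments.
#' @param phred_q Phred quality assigned to every base; the per-base
#'   substitution error rate is `10^(-phred_q/10)` (Q30 = 1 error in 1000).
#' @param clonal_rate Probability that an emitted read is a clonal duplicate;
#'   each unique read spawns `1 + Geometric(1 - clonal_rate)` copies.
#' @param numt_fraction Proportion of molecules that are linear nuclear
#'   fragments carrying an mtDNA-homologous insert (NUMTs).
#' @param repeat_fraction Proportion of molecules that are linear nuclear
#'   fragments of LINE/SINE-like repeat decoys.
#' @param exov_efficiency Probability that exonuclease V destroys a linear
#'   molecule before sequencing (circular mtDNA is protected).
#' @param strand_balance Probability a read is sequenced from the plus
#'   (L) strand; 0.5 is balanced.
#' @param region Optional `c(start, end)` restricting read starts to a window
#'   of the mitochondrial genome (targeted-depth simulation).
#' @param seed Integer seed; all generators are bit-reproducible given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(mean_depth = 500, read_length = 150,
                       read_length_jitter = 40, phred_q = 30,
                       clonal_rate = 0, numt_fraction = 0,
                       repeat_fraction = 0, exov_efficiency = 1,
                       strand_balance = 0.5, region = NULL, seed = 1) {
  props <- c(clonal_rate, numt_fraction, repeat_fraction, exov_efficiency,
             strand_balance)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (mean_depth <= 0 || read_length <= 0) stop("depth and read length must be positive")
  if (read_length_jitter < 0 || read_length_jitter >= read_length)
    stop("read_length_jitter must be in [0, read_length)")
  structure(list(mean_depth = mean_depth, read_length = as.integer(read_length),
                 read_length_jitter = as.integer(read_length_jitter),
                 phred_q = phred_q, base_error = 10^(-phred_q / 10),
                 clonal_rate = clonal_rate, numt_fraction = numt_fraction,
                 repeat_fraction = repeat_fraction,
                 exov_efficiency = exov_efficiency,
                 strand_balance = strand_balance, region = region,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# apply substitutions and single-base-style insertions/deletions to a raw
# sequence string (molecule level; coordinates are pre-variant)
apply_variants_to_seq <- function(sequence, variants) {
  if (is.character(variants)) variants <- parse_variant(variants)
  if (is.null(variants) || nrow(variants) == 0L) return(sequence)
  if (anyDuplicated(variants$position))
    stop("conflicting variants at one position on a single haplotype")
  v <- variants[order(variants$position, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    found <- substring(sequence, p, p + nchar(v$ref[i]) - 1L)
    if (found != v$ref[i])
      stop("reference allele mismatch at ", p, " for ", v$label[i])
    sequence <- paste0(substring(sequence, 1L, p - 1L), v$alt[i],
                       substring(sequence, p + nchar(v$ref[i])))
  }
  sequence
}

#' Build a molecule population
#'
#' Represents the DNA species in a sample: circular mtDNA haplotypes at given
#' fractions, plus linear nuclear fragments — NUMT-bearing fragments (an
#' mtDNA-homologous segment embedded in random nuclear background) and
#' repeat-element decoy fragments. Haplotype fractions apply within the
#' circular compartment; `numt_fraction`/`repeat_fraction` are proportions of
#' all molecules.
#'
#' @param ref A `mito_reference`.
#' @param haplotypes list of `list(variants = <labels or NULL>, fraction =)`;
#'   fractions must sum to 1.
#' @param numt_fraction,repeat_fraction Proportions of all molecules.
#' @param numt_length_range Range of the mtDNA-homologous segment length.
#' @param scale Total molecule count the fractions are realized over.
#' @param seed Seed for NUMT segment placement and nuclear background.
#' @return Object of class `molecule_population`.
#' @export
build_molecule_population <- function(ref, haplotypes, numt_fraction = 0,
                                      repeat_fraction = 0,
                                      numt_length_range = c(500, 5000),
                                      scale = 10000, seed = 1) {
  fr <- vapply(haplotypes, function(h) h$fraction, 0)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("haplotype fractions must sum to 1, got ", sum(fr))
  if (numt_fraction + repeat_fraction > 1)
    stop("nuclear fractions exceed 1")
  set.seed(seed)
  mito_total <- 1 - numt_fraction - repeat_fraction
  rows <- list()
  for (i in seq_along(haplotypes)) {
    h <- haplotypes[[i]]
    v <- if (is.null(h$variants) || length(h$variants) == 0L) NULL else
      parse_variant(h$variants)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("mito_h%02d", i), type = "mito", topology = "circular",
      count = round(scale * mito_total * h$fraction),
      sequence = apply_variants_to_seq(ref$sequence, v),
      variants = I(list(if (is.null(v)) character() else v$label)),
      stringsAsFactors = FALSE)
  }
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  if (numt_fraction > 0) {
    n_species <- 8L
    for (i in seq_len(n_species)) {
      seg_len <- sample(numt_length_range[1]:numt_length_range[2], 1L)
      seg_start <- sample(ref$length, 1L)
      insert <- ref_segment(ref, seg_start, seg_len)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("numt_%02d", i), type = "numt", topology = "linear",
        count = round(scale * numt_fraction / n_species),
        sequence = paste0(rand_seq(300L), insert, rand_seq(300L)),
        variants = I(list(character())), stringsAsFactors = FALSE)
    }
  }
  if (repeat_fraction > 0) {
    decoys <- synthetic_repeat_library()
    for (i in seq_along(decoys)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("repeat_%02d", i), type = "repeat", topology = "linear",
        count = round(scale * repeat_fraction / length(decoys)),
        sequence = unname(decoys[i]),
        variants = I(list(character())), stringsAsFactors = FALSE)
    }
  }
  structure(list(molecules = do.call(rbind, rows), scale = scale,
                 ref_name = ref$name, ref_length = ref$length),
            class = "molecule_population")
}

#' Digest linear molecules with exonuclease V
#'
#' Each linear molecule is independently destroyed with probability
#' `efficiency`; circular molecules are untouched. This is the enrichment step
#' that protects circular mtDNA while eliminating NUMT-bearing nuclear
#' fragments.
#'
#' @param pop A `molecule_population`.
#' @param efficiency Digestion probability in \[0, 1\].
#' @param seed Seed for the binomial survival draws.
#' @return The thinned `molecule_population`.
#' @export
apply_exov <- function(pop, efficiency, seed = 1) {
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  set.seed(seed)
  lin <- pop$molecules$topology == "linear"
  pop$molecules$count[lin] <-
    stats::rbinom(sum(lin), pop$molecules$count[lin], 1 - efficiency)
  pop
}

#' Simulate sequencing reads from a molecule population
#'
#' Reads are sampled uniformly around circular molecules (wrapping the
#' origin) and uniformly along linear fragments, weighted by molecule count.
#' Bases are perturbed by a uniform substitution error at the phred-implied
#' rate; quality strings are the corresponding constant phred+33 encoding.
#' Clonal duplicates share a clonal-group id with their source read.
#' Deterministic given `cfg$seed`.
#'
#' @param pop A `molecule_population`.
#' @param cfg A [sim_config()].
#' @return list of class `sim_reads`: `reads` (data.frame `id`, `seq`,
#'   `qual`), `truth` (per-read provenance: molecule id, type, strand,
#'   leftmost reference start, clonal group, duplicate flag), `config`.
#' @export
simulate_reads <- function(pop, cfg) {
  set.seed(cfg$seed)
  mol <- pop$molecules[pop$molecules$count > 0L, , drop = FALSE]
  if (nrow(mol) == 0L) stop("population contains no molecules")
  rl <- cfg$read_length
  L <- pop$ref_length
  if (rl >= L) stop("read length incompatible with genome length")
  if (!is.null(cfg$region)) {
    mol <- mol[mol$type == "mito", , drop = FALSE]
    span <- cfg$region[2] - cfg$region[1] + 1L
    n_reads <- round(cfg$mean_depth * span / rl)
  } else {
    n_reads <- round(cfg$mean_depth * L / rl)
  }
  pick <- sample.int(nrow(mol), n_reads, replace = TRUE, prob = mol$count)
  read_len <- rl - sample.int(cfg$read_length_jitter + 1L, n_reads,
                              replace = TRUE) + 1L
  mol_len <- nchar(mol$sequence)
  circular <- mol$topology == "circular"
  start <- integer(n_reads)
  for (m in unique(pick)) {
    idx <- which(pick == m)
    if (circular[m]) {
      if (!is.null(cfg$region)) {
        lo <- cfg$region[1] - rl + 1L
        start[idx] <- sample(lo:cfg$region[2], length(idx), replace = TRUE)
        start[idx] <- wrap_pos(start[idx], mol_len[m])
      } else {
        start[idx] <- sample.int(mol_len[m], length(idx), replace = TRUE)
      }
    } else {
      start[idx] <- sample.int(max(1L, mol_len[m] - rl + 1L), length(idx),
                               replace = TRUE)
    }
  }
  # extract read sequences (doubled string handles the origin wrap)
  seqs <- character(n_reads)
  for (m in unique(pick)) {
    idx <- which(pick == m)
    src <- if (circular[m])
      paste0(mol$sequence[m], substring(mol$sequence[m], 1L, rl)) else
      mol$sequence[m]
    seqs[idx] <- substring(src, start[idx],
                           pmin(start[idx] + read_len[idx] - 1L, nchar(src)))
  }
  strand <- ifelse(stats::runif(n_reads) < cfg$strand_balance, "plus", "minus")

  # uniform per-base substitution errors at the phred-implied rate
  n_err <- stats::rbinom(n_reads, nchar(seqs), cfg$base_error)
  for (i in which(n_err > 0L)) {
    p <- sample.int(nchar(seqs[i]), n_err[i])
    for (j in p) {
      old <- substring(seqs[i], j, j)
      substring(seqs[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  minus <- strand == "minus"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  copies <- 1L + stats::rgeom(n_reads, 1 - cfg$clonal_rate)
  rep_idx <- rep(seq_len(n_reads), copies)
  ids <- sprintf("r%07d", seq_along(rep_idx))
  qual_chr <- rawToChar(as.raw(33L + cfg$phred_q))
  quals <- vapply(nchar(seqs[rep_idx]), function(n)
    strrep(qual_chr, n), "")
  truth <- data.frame(
    read_id = ids,
    molecule = mol$id[pick][rep_idx],
    type = mol$type[pick][rep_idx],
    strand = strand[rep_idx],
    start = start[rep_idx],
    clonal_group = sprintf("c%07d", rep_idx),
    duplicate = duplicated(rep_idx),
    stringsAsFactors = FALSE)
  structure(list(reads = data.frame(id = ids, seq = seqs[rep_idx],
                                    qual = quals, stringsAsFactors = FALSE),
                 truth = truth, config = cfg),
            class = "sim_reads")
}

#' Write reads to FASTQ (phred+33)
#'
#' @param x A `sim_reads` object or a data.frame with `id`, `seq`, `qual`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(x, path) {
  reads <- if (inherits(x, "sim_reads")) x$reads else x
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = sub(" .*", "", names(dna)),
             seq = as.character(dna),
             qual = as.character(S4Vectors::mcols(dna)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a matched peri-normal/tumor read-set pair
#'
#' The normal sample carries the germline variants homoplasmically; the tumor
#' carries germline plus each tumor-only variant at its specified fraction.
#' Tumor-only fractions are realized as an independent-site mixture: all
#' 2^k combinations of the k tumor-only variants become explicit haplotypes
#' with product weights, so each variant's marginal fraction is exact even
#' when the fractions sum to more than 1 (variants on different molecules).
#'
#' @param ref A `mito_reference`.
#' @param germline_variants Character vector of germline variant labels.
#' @param tumor_only data.frame with columns `label` and `fraction`.
#' @param cfg A [sim_config()]; the tumor sample uses `cfg$seed + 1`.
#' @return list with `normal` and `tumor` (`sim_reads`) and `truth`
#'   (the tumor-only variants with their true fractions).
#' @export
make_matched_pair_dataset <- function(ref, germline_variants, tumor_only,
                                      cfg) {
  if (is.null(tumor_only) || nrow(tumor_only) == 0L) {
    tumor_only <- data.frame(label = character(), fraction = numeric())
  }
  k <- nrow(tumor_only)
  if (k > 12L) stop("at most 12 tumor-only variants supported")
  gpos <- if (length(germline_variants))
    parse_variant(germline_variants)$position else integer()
  tpos <- if (k) parse_variant(tumor_only$label)$position else integer()
  if (length(intersect(gpos, tpos)))
    stop("germline and tumor-only variant sets overlap in position")

  normal_pop <- build_molecule_population(
    ref, list(list(variants = germline_variants, fraction = 1)),
    numt_fraction = cfg$numt_fraction, repeat_fraction = cfg$repeat_fraction,
    seed = cfg$seed)
  haps <- list()
  if (k == 0L) {
    haps <- list(list(variants = germline_variants, fraction = 1))
  } else {
    for (mask in 0:(2^k - 1L)) {
      inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      frac <- prod(ifelse(inset, tumor_only$fraction, 1 - tumor_only$fraction))
      if (frac == 0) next
      haps[[length(haps) + 1L]] <- list(
        variants = c(germline_variants, tumor_only$label[inset]),
        fraction = frac)
    }
  }
  tumor_pop <- build_molecule_population(
    ref, haps, numt_fraction = cfg$numt_fraction,
    repeat_fraction = cfg$repeat_fraction, seed = cfg$seed + 1L)
  tumor_cfg <- cfg
  tumor_cfg$seed <- cfg$seed + 1L
  list(normal = simulate_reads(normal_pop, cfg),
       tumor = simulate_reads(tumor_pop, tumor_cfg),
       truth = tumor_only)
}

#' Generate a read-count table of tumor/normal variant and wild-type reads
#'
#' Emulates published per-variant read-count tables from exome-style mtDNA
#' reanalysis: each row carries tumor variant/WT read counts and matched
#' normal variant/WT counts. The truth table marks which rows survive the
#' count filters (either tumor count > cutoff, normal WT > cutoff, normal
#' heteroplasmy below the residual cutoff).
#'
#' @param ref A `mito_reference` (variant labels are drawn against it).
#' @param n_samples Number of tumor sample indexes.
#' @param mean_coverage Mean read depth for the count draws.
#' @param low_count_rate Probability a tumor or normal total is drawn shallow
#'   (exercises the count filter).
#' @param high_normal_het_rate Probability a normal sample carries residual
#'   heteroplasmy above 0.4% (exercises the residual filter).
#' @param seed Integer seed.
#' @param count_cutoff,normal_het_cutoff Filters used for the truth marks.
#' @return list with `records` (the table) and `truth` (`retained` flag and
#'   tumor heteroplasmy percent per row).
#' @export
make_ju_table <- function(ref, n_samples = 10, mean_coverage = 800,
                          low_count_rate = 0.15, high_normal_het_rate = 0.1,
                          seed = 1, count_cutoff = 100,
                          normal_het_cutoff = 0.4) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (v in seq_len(sample(1:3, 1L))) {
      pos <- sample(ref$length, 1L)
      refb <- ref_base(ref, pos)
      if (refb == "N") next
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      tumor_total <- if (stats::runif(1) < low_count_rate)
        sample(20:100, 1L) else stats::rpois(1L, mean_coverage)
      normal_total <- if (stats::runif(1) < low_count_rate)
        sample(20:100, 1L) else stats::rpois(1L, mean_coverage)
      frac <- stats::runif(1, 0.05, 1)
      normal_het <- if (stats::runif(1) < high_normal_het_rate)
        stats::runif(1, 0.4, 2) else stats::runif(1, 0, 0.3)
      tv <- stats::rbinom(1L, tumor_total, frac)
      nv <- stats::rbinom(1L, normal_total, normal_het / 100)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_index = 5000L + s,
        variant = paste0(refb, pos, alt),
        tumor_variant_reads = tv, tumor_wt_reads = tumor_total - tv,
        normal_variant_reads = nv, normal_wt_reads = normal_total - nv,
        true_fraction = frac, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  het <- 100 * records$tumor_variant_reads /
    (records$tumor_variant_reads + records$tumor_wt_reads)
  normal_het_obs <- 100 * records$normal_variant_reads /
    (records$normal_variant_reads + records$normal_wt_reads)
  truth <- data.frame(
    sample_index = records$sample_index, variant = records$variant,
    heteroplasmy = het,
    retained = pmax(records$tumor_variant_reads, records$tumor_wt_reads) >
      count_cutoff & records$normal_wt_reads > count_cutoff &
      normal_het_obs < normal_het_cutoff,
    stringsAsFactors = FALSE)
  list(records = records[, 1:6], truth = truth)
}

#' Generate synthetic densitometry lane profiles
#'
#' Each lane is a 1-D Gaussian-mixture intensity profile: every band
#' contributes `area * dnorm(position, center, width)`, plus optional additive
#' noise (clamped at zero, as scanned intensities are non-negative). The truth
#' table records the per-band areas; bands whose centers lie closer than the
#' sum of their widths are flagged unresolvable.
#'
#' @param band_spec data.frame with columns `center`, `width`, `area`
#'   (one lane), or a list of such data.frames (one per lane).
#' @param lane_count Number of lanes (recycled spec if a single data.frame).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param positions Sampling grid along the lane.
#' @param seed Integer seed for the noise.
#' @return list with `profiles` (data.frame `lane`, `position`, `intensity`)
#'   and `truth` (per-lane, per-band `area` and `resolvable` flag).
#' @export
make_lane_profiles <- function(band_spec, lane_count = 1, noise_sd = 0,
                               positions = seq(0, 100, by = 0.05), seed = 1) {
  if (noise_sd < 0) stop("noise sd must be non-negative")
  specs <- if (is.data.frame(band_spec))
    rep(list(band_spec), lane_count) else band_spec
  if (length(specs) != lane_count)
    stop("band_spec list length must equal lane_count")
  set.seed(seed)
  profiles <- list(); truth <- list()
  for (l in seq_len(lane_count)) {
    sp <- specs[[l]]
    if (any(sp$width <= 0) || any(sp$area < 0)) stop("degenerate band spec")
    y <- rep(0, length(positions))
    for (b in seq_len(nrow(sp)))
      y <- y + sp$area[b] * stats::dnorm(positions, sp$center[b], sp$width[b])
    if (noise_sd > 0) y <- pmax(0, y + stats::rnorm(length(y), 0, noise_sd))
    profiles[[l]] <- data.frame(lane = l, position = positions, intensity = y)
    resolvable <- rep(TRUE, nrow(sp))
    if (nrow(sp) > 1L) for (b in seq_len(nrow(sp)))
      for (b2 in setdiff(seq_len(nrow(sp)), b))
        if (abs(sp$center[b] - sp$center[b2]) < sp$width[b] + sp$width[b2])
          resolvable[b] <- FALSE
    truth[[l]] <- data.frame(lane = l, band = seq_len(nrow(sp)),
                             center = sp$center, area = sp$area,
                             resolvable = resolvable)
  }
  list(profiles = do.call(rbind, profiles), truth = do.call(rbind, truth))
}
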