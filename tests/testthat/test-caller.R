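test_that("quality filtering removes only runs longer than the threshold", {
  seqs <- rep(strrep("A", 40), 3)
  quals <- c(paste0(qstr(40, 10), qstr(15, 11), qstr(40, 19)),  # 11-run: out
             paste0(qstr(40, 10), qstr(15, 10), qstr(40, 20)),  # 10-run: kept
             qstr(40, 40))                                      # clean: kept
  reads <- data.frame(id = c("a", "b", "c"), seq = seqs, qual = quals,
                      stringsAsFactors = FALSE)
  out <- filter_read_quality(reads)
  expect_equal(out$discarded$id, "a")
  expect_equal(out$retained$id, c("b", "c"))
  bad <- reads; bad$qual[1] <- ""
  expect_error(filter_read_quality(bad), "malformed")
})

test_that("reads spanning the origin map across the junction", {
  r <- reads_df(ref_segment(REF, 16560L, 20L))
  al <- map_circular(r, REF)
  expect_equal(al$aligned$start, 16560L)
  expect_equal(al$aligned$strand, "plus")
  # its reverse complement maps to the same start on the minus strand
  rc <- reads_df(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref_segment(REF, 16560L, 20L)))))
  al2 <- map_circular(rc, REF)
  expect_equal(al2$aligned$start, 16560L)
  expect_equal(al2$aligned$strand, "minus")
})

test_that("decoy-matching reads are labeled repeat-decoy, not dropped", {
  decoys <- synthetic_repeat_library()
  r <- reads_df(c(substring(decoys[[1]], 101, 180),
                  ref_segment(REF, 1000L, 80L),
                  strrep("ACGT", 20)))
  al <- map_circular(r, REF, decoys = decoys)
  expect_equal(al$sources$source, c("repeat-decoy", "mito", "unmapped"))
  expect_equal(nrow(al$aligned), 1L)
})

test_that("error-free simulated reads map to their truth provenance", {
  pop <- build_molecule_population(REF, list(list(variants = NULL, fraction = 1)))
  cfg <- sim_config(mean_depth = 15, phred_q = 40, seed = 31)
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  al <- map_circular(sim$reads, REF)
  expect_equal(nrow(al$aligned), nrow(sim$reads))  # 100% mapped
  m <- merge(al$aligned, sim$truth, by.x = "id", by.y = "read_id")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$strand.x, m$strand.y)
})

test_that("clonal collapsing keeps one representative per identical read", {
  base <- ref_segment(REF, 501L, 60L)
  variant_read <- base
  substring(variant_read, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                             substring(base, 30, 30))[1]
  r <- reads_df(c(rep(base, 5), variant_read))
  al <- map_circular(r, REF)
  col <- collapse_clonal(al)
  expect_equal(nrow(col$aligned), 2L)
  expect_setequal(col$multiplicity$count, c(5L, 1L))

  # simulator round-trip: representatives equal the truth non-clonal count
  pop <- build_molecule_population(REF, list(list(variants = NULL, fraction = 1)))
  cfg <- sim_config(mean_depth = 10, clonal_rate = 0.25, phred_q = 40, seed = 17)
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  col2 <- collapse_clonal(map_circular(sim$reads, REF))
  expect_equal(nrow(col2$aligned),
               length(unique(sim$truth$clonal_group)))
})

test_that("contamination estimation applies the repeat calibration", {
  fake <- list(sources = data.frame(
    id = sprintf("r%d", 1:100),
    source = c(rep("repeat-decoy", 15), rep("mito", 85)),
    stringsAsFactors = FALSE))
  est <- estimate_contamination(fake, repeat_genomic_fraction = 0.3)
  expect_equal(est$nuclear_fraction, 0.5)
  fake$sources$source <- "mito"
  expect_equal(estimate_contamination(fake, 0.3)$nuclear_fraction, 0)
  expect_error(estimate_contamination(list(sources = fake$sources[0, ]), 0.3),
               "no reads")
  expect_error(estimate_contamination(fake, 0), "must be in")
})

test_that("a known nuclear fraction is recovered within 0.05", {
  f <- 0.2
  pop <- build_molecule_population(
    REF, list(list(variants = NULL, fraction = 1)),
    numt_fraction = 0.7 * f, repeat_fraction = 0.3 * f)
  pop <- apply_exov(pop, 0)  # no digestion: contamination survives
  cfg <- sim_config(mean_depth = 60, phred_q = 40, seed = 23)
  sim <- simulate_reads(pop, cfg)
  al <- map_circular(sim$reads, REF, decoys = synthetic_repeat_library())
  est <- estimate_contamination(al, repeat_genomic_fraction = 0.3)
  expect_lt(abs(est$nuclear_fraction - f), 0.05)
})

test_that("pileup counts agree with a brute-force per-read recount", {
  set.seed(5)
  starts <- sample(REF$length - 100L, 40L)
  seqs <- vapply(starts, function(s) ref_segment(REF, s, 60L), "")
  # plant some alternate alleles
  for (i in 1:10) substring(seqs[i], 20, 20) <-
      setdiff(c("A", "C", "G", "T"), substring(seqs[i], 20, 20))[1]
  r <- reads_df(seqs)
  al <- map_circular(r, REF)
  pl <- build_pileup(al, REF)
  oracle <- pileup_oracle(al, REF)
  expect_equal(pl$cov_plus, unname(oracle$cov[, "plus"]))
  expect_equal(pl$cov_minus, unname(oracle$cov[, "minus"]))
  for (i in seq_len(nrow(pl$alts))) {
    a <- pl$alts[i, ]
    if (a$style != "substitution") next
    if (a$plus > 0)
      expect_equal(a$plus, oracle$alt[[paste(a$pos, a$allele, "plus")]])
    if (a$minus > 0)
      expect_equal(a$minus, oracle$alt[[paste(a$pos, a$allele, "minus")]])
  }
  # single read covers exactly its span
  one <- build_pileup(map_circular(reads_df(ref_segment(REF, 1L, 50L)), REF), REF)
  expect_equal(sum(one$cov_plus), 50L)
  expect_equal(sum(one$cov_minus), 0L)
})

test_that("filter statuses follow the support, coverage, skew and blacklist rules", {
  mk_pileup <- function(pos, plus, minus, cov_plus, cov_minus) {
    cp <- integer(REF$length); cm <- integer(REF$length)
    cp[pos] <- cov_plus; cm[pos] <- cov_minus
    structure(list(cov_plus = cp, cov_minus = cm,
                   alts = data.frame(pos = pos, allele = "A",
                                     style = "substitution", plus = plus,
                                     minus = minus, stringsAsFactors = FALSE),
                   ref = REF), class = "mito_pileup")
  }
  # 2 supporting reads at coverage 500: insufficient support
  c1 <- call_variants(mk_pileup(1000L, 1L, 1L, 250L, 250L))
  expect_equal(c1$filter, "low_support")
  # 40 supporting reads, 39 on the plus strand: skew 0.025 < 0.1
  c2 <- call_variants(mk_pileup(1000L, 39L, 1L, 250L, 250L))
  expect_equal(c2$filter, "strand_skew")
  expect_equal(c2$skew, 1 / 40)
  # balanced, well-supported: PASS, with the plus-strand percent convention
  c3 <- call_variants(mk_pileup(1000L, 50L, 50L, 200L, 200L))
  expect_equal(c3$filter, "PASS")
  expect_equal(c3$vaf_plus, 25)
  expect_equal(c3$vaf_both, 25)
  # coverage below 10
  c4 <- call_variants(mk_pileup(1000L, 3L, 3L, 4L, 4L))
  expect_equal(c4$filter, "low_coverage")
  # blacklist window 302-315 can never PASS
  c5 <- call_variants(mk_pileup(310L, 50L, 50L, 200L, 200L))
  expect_equal(c5$filter, "blacklist")
  expect_error(call_variants(mk_pileup(1000L, 5L, 5L, 20L, 20L),
                             min_support = 0), "positive")
})

test_that("clonal duplication never changes a variant call", {
  base <- ref_segment(REF, 2001L, 80L)
  alt_read <- base
  substring(alt_read, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                         substring(base, 40, 40))[1]
  shifted <- vapply(2001L + 1:12, function(s) ref_segment(REF, s, 80L), "")
  alt_shift <- vapply(2001L + 1:6, function(s) {
    x <- ref_segment(REF, s, 80L)
    substring(x, 2040 - s + 1, 2040 - s + 1) <- substring(alt_read, 40, 40)
    x
  }, "")
  plain <- c(base, shifted, alt_read, alt_shift)
  dup <- c(plain, rep(alt_read, 7), rep(base, 4))  # clonal copies added
  call_of <- function(seqs) {
    al <- collapse_clonal(map_circular(reads_df(seqs), REF))
    call_variants(build_pileup(al, REF), min_coverage = 5)
  }
  expect_equal(call_of(plain), call_of(dup))
})

test_that("raising thresholds never enlarges the PASS set", {
  pop <- build_molecule_population(REF, list(
    list(variants = NULL, fraction = 0.6),
    list(variants = c("T6481C", "G15995A"), fraction = 0.4)))
  cfg <- sim_config(mean_depth = 40, phred_q = 40, seed = 9)
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  pl <- build_pileup(collapse_clonal(map_circular(sim$reads, REF)), REF)
  pass <- function(...) {
    cc <- call_variants(pl, ...)
    cc$label[cc$filter == "PASS"]
  }
  base <- pass()
  expect_true(all(pass(min_support = 8) %in% base))
  expect_true(all(pass(min_coverage = 30) %in% base))
  expect_true(all(pass(min_support = 8, min_coverage = 30) %in% base))
})

test_that("error-free balanced simulations yield no false PASS calls", {
  truth <- c("T6481C", "G15995A", "C16327T")
  pop <- build_molecule_population(REF, list(
    list(variants = NULL, fraction = 0.5),
    list(variants = truth, fraction = 0.5)))
  cfg <- sim_config(mean_depth = 60, phred_q = 40, clonal_rate = 0.1, seed = 77)
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  res <- call_pipeline(sim$reads, REF)
  pass <- res$calls[res$calls$filter == "PASS", ]
  expect_setequal(pass$label, truth)
  expect_true(all(abs(pass$vaf_both - 50) < 15))
})

test_that("percent-variant converges to the truth fraction with depth", {
  frac <- 0.7
  pop <- build_molecule_population(REF, list(
    list(variants = NULL, fraction = 1 - frac),
    list(variants = "T6481C", fraction = frac)))
  tol <- c(`100` = 20, `1000` = 6, `10000` = 2.5)
  for (depth in c(100, 1000, 10000)) {
    cfg <- sim_config(mean_depth = depth, phred_q = 40, seed = 3,
                      region = c(6100, 6900))
    cfg$base_error <- 0
    sim <- simulate_reads(pop, cfg)
    res <- call_pipeline(sim$reads, REF)
    v <- res$calls[res$calls$label == "T6481C", ]
    expect_equal(v$filter, "PASS")
    expect_lt(abs(v$vaf_both - 100 * frac), tol[[as.character(depth)]])
  }
})

test_that("coincident-error probabilities follow the power law", {
  expect_equal(coincident_error_probability(1e-3, 2), 1e-6)
  expect_equal(coincident_error_probability(1e-3, 3), 1e-9)
  p <- 0.0042
  expect_equal(coincident_error_probability(p, 1), p)
  expect_error(coincident_error_probability(0, 2), "per_base_error")
  expect_error(coincident_error_probability(1e-3, 0), "n_reads")
})

test_that("single-base insertions are called with the anchor-base label", {
  pop <- build_molecule_population(REF, list(
    list(variants = NULL, fraction = 0.5),
    list(variants = "C5899CC", fraction = 0.5)))
  cfg <- sim_config(mean_depth = 120, phred_q = 40, seed = 19,
                    region = c(5400, 6400))
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  res <- call_pipeline(sim$reads, REF)
  ins <- res$calls[res$calls$style == "insertion" & res$calls$filter == "PASS", ]
  expect_equal(ins$label, "C5899CC")
  # reads whose inserted base sits within a few bases of a read end carry no
  # unambiguous evidence (the run merely looks shifted), so the called
  # fraction sits somewhat below the molecular truth
  expect_lt(abs(ins$vaf_both - 50), 15)
  # every carrier with the inserted base well inside the read is recovered
  lens <- nchar(sim$reads$seq)
  interior <- sim$truth$molecule == "mito_h02" &
    sim$truth$start <= 5900 - 9 & sim$truth$start + lens - 1 >= 5900 + 9
  expect_true(all(sim$reads$id[interior] %in% res$alignment$insertions$id))
})

test_that("the VCF writer emits parseable VCFv4 with the INFO fields", {
  pop <- build_molecule_population(REF, list(
    list(variants = NULL, fraction = 0.5),
    list(variants = "T6481C", fraction = 0.5)))
  cfg <- sim_config(mean_depth = 30, phred_q = 40, seed = 2)
  cfg$base_error <- 0
  sim <- simulate_reads(pop, cfg)
  res <- call_pipeline(sim$reads, REF)
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(res$calls, REF, path)
  vcf <- VariantAnnotation::readVcf(path, genome = "mito")
  expect_equal(nrow(vcf), nrow(res$calls))
  expect_true("T6481C" %in% names(SummarizedExperiment::rowRanges(vcf)))
  expect_equal(unname(VariantAnnotation::info(vcf)$DP),
               res$calls$coverage)
})
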