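test_that("bundled reference has the canonical structure", {
  expect_equal(REF$length, 16569L)
  genes <- REF$features[REF$features$kind %in% c("protein", "tRNA", "rRNA"), ]
  expect_equal(length(unique(genes$name)), 37L)
  expect_equal(sum(genes$kind == "protein"), 13L)
  expect_equal(sum(genes$kind == "tRNA"), 22L)
  expect_equal(sum(genes$kind == "rRNA"), 2L)
  # mitochondrial code departures from the nuclear code
  expect_equal(unname(REF$code[c("AGA", "AGG", "ATA", "TGA")]),
               c("*", "*", "M", "W"))
})

test_that("circular indexing resolves positions across the origin", {
  expect_equal(nrow(locate_features(REF, 16569L)) > 0L, TRUE)
  expect_equal(nrow(locate_features(REF, 1L)) > 0L, TRUE)
  expect_error(locate_features(REF, 0L), "position")
  expect_error(locate_features(REF, 16570L), "position")
  # segment wrapping the origin equals the concatenated ends
  expect_equal(ref_segment(REF, 16565L, 10L),
               paste0(substring(REF$sequence, 16565, 16569),
                      substring(REF$sequence, 1, 5)))
  expect_equal(ref_base(REF, 16570L), ref_base(REF, 1L))
})

test_that("regenerating the synthetic reference reproduces the fixture", {
  regen <- synthesize_reference()
  expect_identical(regen$sequence, REF$sequence)
  expect_identical(regen$features$start, REF$features$start)
})

test_that("feature lookup matches the printed gene assignments", {
  expect_true("ND5" %in% locate_features(REF, 13417)$name)
  expect_true("COX1" %in% locate_features(REF, 6481)$name)
  hits <- locate_features(REF, 5899)
  expect_equal(hits$name, "NC5")
  expect_equal(hits$kind, "noncoding")
})

test_that("all protein genes translate without internal stops", {
  prot <- unique(REF$features$name[REF$features$kind == "protein"])
  lens <- vapply(prot, function(g) nchar(translate_mito(REF, g)), 0L)
  cds_codons <- vapply(prot, function(g) {
    f <- REF$features[REF$features$name == g, ][1L, ]
    (f$end - f$start + 1L) %/% 3L
  }, 0L)
  # a premature internal stop would shorten the protein below its CDS capacity
  expect_true(all(lens >= cds_codons - 1L))
  expect_equal(unname(lens["ND5"]), 603L)
  expect_error(translate_mito(REF, "TRNF"), "not a protein")
})

test_that("the ND5 nonsense substitution truncates 603 residues to 360", {
  mutant <- apply_substitutions(REF, "G13417A")
  expect_equal(nchar(translate_mito(REF, "ND5")), 603L)
  expect_equal(nchar(translate_mito(mutant, "ND5")), 360L)
  ann <- consequence_of(REF, "G13417A")
  expect_equal(ann$consequence, "nonsense")
  expect_equal(ann$aa_change, "G361TERM")
  expect_equal(ann$truncated_length, 360L)
})

test_that("a stop in the second codon truncates translation to one residue", {
  # engineer AGA (mitochondrial stop) as codon 2 of ND3
  p <- 10062:10064
  cur <- ref_base(REF, p)
  want <- c("A", "G", "A")
  labels <- paste0(cur[cur != want], p[cur != want], want[cur != want])
  mutant <- apply_substitutions(REF, labels)
  expect_equal(nchar(translate_mito(mutant, "ND3")), 1L)
})

test_that("consequence annotation reproduces the printed variant effects", {
  a <- consequence_of(REF, "T6481C")
  expect_equal(a$feature, "COX1")
  expect_equal(a$consequence, "missense")
  expect_equal(a$aa_change, "V193A")
  expect_equal(a$spectrum_class, "T>C")
  expect_true(a$transition)

  b <- consequence_of(REF, "G12007A")
  expect_equal(b$consequence, "synonymous")
  expect_equal(b$aa_change, "W416W")
  expect_true(b$transition)

  d <- consequence_of(REF, "A10411T")
  expect_equal(d$feature, "TRNR")
  expect_equal(d$consequence, "tRNA")
  expect_false(d$transition)

  ins <- consequence_of(REF, "C5899CC")
  expect_equal(ins$feature, "NC5")
  expect_equal(ins$consequence, "noncoding")
  expect_equal(ins$spectrum_class, "insertion")

  # H-strand-encoded gene: L-strand G>A label, complementary codon change
  e <- consequence_of(REF, "G14410A")
  expect_equal(e$feature, "ND6")
  expect_equal(e$consequence, "synonymous")
  expect_equal(e$aa_change, "V88V")
  expect_equal(e$spectrum_class, "G>A")

  expect_error(consequence_of(REF, paste0("X")), "malformed")
  wrong <- paste0(setdiff(c("A", "C", "G", "T"), ref_base(REF, 6481))[1],
                  6481, "G")
  expect_error(consequence_of(REF, wrong), "mismatch")
})

test_that("variants in overlapping genes report all features", {
  # ATP8/ATP6 dicistronic overlap spans 8527..8572
  pos <- 8540L
  refb <- ref_base(REF, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  ann <- consequence_of(REF, paste0(refb, pos, alt))
  expect_setequal(ann$feature, c("ATP8", "ATP6"))
})

test_that("consequence annotation is involution-safe", {
  set.seed(11)
  pos <- sample(REF$length, 40L)
  for (p in pos) {
    refb <- ref_base(REF, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    fwd <- consequence_of(REF, paste0(refb, p, alt))
    mutant <- apply_substitutions(REF, paste0(refb, p, alt))
    rev <- consequence_of(mutant, paste0(alt, p, refb))
    fm <- fwd[fwd$kind == "protein" & fwd$consequence %in%
                c("missense", "synonymous"), ]
    rm_ <- rev[rev$kind == "protein" & rev$consequence %in%
                 c("missense", "synonymous"), ]
    if (nrow(fm) && nrow(rm_)) {
      swap <- function(x) sub("^([A-Z])([0-9]+)([A-Z])$", "\\3\\2\\1", x)
      expect_equal(sort(rm_$aa_change), sort(swap(fm$aa_change)))
    }
  }
})

test_that("spectrum classes partition substitutions; transitions match a base-category oracle", {
  set.seed(7)
  pos <- sample(REF$length, 200L, replace = TRUE)
  refb <- ref_base(REF, pos)
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  cls <- spectrum_class(refb, alt)
  classes12 <- unique(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      function(a, b) paste0(a, ">", b))))
  counts <- table(factor(cls, levels = classes12))
  expect_equal(sum(counts), length(pos))  # every substitution in one class
  purine <- c("A", "G")
  oracle <- (refb %in% purine) == (alt %in% purine)
  expect_equal(is_transition(cls), oracle)
})

test_that("homopolymer runs are counted circularly", {
  r <- homopolymer_run(REF, 5899)
  expect_equal(r$length, 5L)
  expect_equal(r$base, "C")
  # brute-force oracle agreement, including across the origin junction
  for (p in c(5895L, 5899L, 16568L, 16569L, 1L, 2L, 100L, 8000L)) {
    expect_equal(homopolymer_run(REF, p), homopolymer_oracle(REF, p),
                 info = paste("pos", p))
  }
  run_origin <- homopolymer_run(REF, 16569L)
  expect_gte(run_origin$length, 4L)  # engineered A-run straddles the junction
  # isolated base
  iso <- which(diff(utf8ToInt(REF$sequence)) != 0)
  expect_error(homopolymer_run(REF, 0L), "position")
})

test_that("variant labels parse into the three styles", {
  v <- parse_variant(c("T6481C", "C5899CC", "CA5899C"))
  expect_equal(v$style, c("substitution", "insertion", "deletion"))
  expect_equal(v$position, c(6481L, 5899L, 5899L))
  expect_error(parse_variant("T6481T"), "identical")
  expect_error(parse_variant("6481C"), "malformed")
})

test_that("reference loading validates its inputs", {
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa2)
  tsv <- system.file("extdata", "synthetic_rCRS_features.tsv",
                     package = "mseekr")
  expect_error(load_reference(fa2, tsv), "exactly one record")

  # a feature table leaving part of the sequence uncovered is rejected
  feats <- utils::read.delim(tsv)
  short <- feats[feats$name != "CR", ]
  bad_tsv <- tempfile(fileext = ".tsv")
  utils::write.table(short, bad_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- system.file("extdata", "synthetic_rCRS.fasta", package = "mseekr")
  expect_error(load_reference(fa, bad_tsv), "span")

  # protein overlap without the explicit flag is rejected
  noflag <- feats
  noflag$overlap_ok[noflag$name %in% c("ATP8", "ATP6")] <- FALSE
  bad_tsv2 <- tempfile(fileext = ".tsv")
  utils::write.table(noflag, bad_tsv2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_reference(fa, bad_tsv2), "overlap")
})
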