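# Deterministic construction of the bundled synthetic reference.
#
# The sequence emulates the rCRS (NC_012920.1) at the structural level: length
# 16,569, the authentic 37-gene map (13 protein / 22 tRNA / 2 rRNA genes plus
# named non-coding stretches, the L-strand genes ND6 and 8 tRNAs, the
# ATP8/ATP6 and ND4L/ND4 dicistronic overlaps, incomplete stop codons), and
# engineered codons/bases at every position the worked examples touch. Filler
# bases are random under a fixed seed. It is NOT the human sequence.

mito_feature_table <- function() {
  f <- function(name, kind, start, end, strand = "H", incomplete = FALSE,
                overlap = FALSE)
    data.frame(name = name, kind = kind, start = as.integer(start),
               end = as.integer(end), strand = strand, frame = 0L,
               incomplete_stop = incomplete, overlap_ok = overlap,
               stringsAsFactors = FALSE)
  rbind(
    f("CR",    "noncoding",     1,   576, "-"),
    f("TRNF",  "tRNA",        577,   647),
    f("RNR1",  "rRNA",        648,  1601),
    f("TRNV",  "tRNA",       1602,  1670),
    f("RNR2",  "rRNA",       1671,  3229),
    f("TRNL1", "tRNA",       3230,  3304),
    f("NC1",   "noncoding",  3305,  3306, "-"),
    f("ND1",   "protein",    3307,  4262, incomplete = TRUE),
    f("TRNI",  "tRNA",       4263,  4331),
    f("TRNQ",  "tRNA",       4329,  4400, "L"),
    f("NC2",   "noncoding",  4401,  4401, "-"),
    f("TRNM",  "tRNA",       4402,  4469),
    f("ND2",   "protein",    4470,  5511, incomplete = TRUE),
    f("TRNW",  "tRNA",       5512,  5579),
    f("NC3",   "noncoding",  5580,  5586, "-"),
    f("TRNA",  "tRNA",       5587,  5655, "L"),
    f("NC4",   "noncoding",  5656,  5656, "-"),
    f("TRNN",  "tRNA",       5657,  5729, "L"),
    f("O_L",   "noncoding",  5721,  5798, "-"),
    f("TRNC",  "tRNA",       5761,  5826, "L"),
    f("TRNY",  "tRNA",       5826,  5891, "L"),
    f("NC5",   "noncoding",  5892,  5903, "-"),
    f("COX1",  "protein",    5904,  7445),
    f("TRNS1", "tRNA",       7446,  7514, "L"),
    f("NC6",   "noncoding",  7515,  7517, "-"),
    f("TRND",  "tRNA",       7518,  7585),
    f("COX2",  "protein",    7586,  8269),
    f("NC7",   "noncoding",  8270,  8294, "-"),
    f("TRNK",  "tRNA",       8295,  8364),
    f("NC8",   "noncoding",  8365,  8365, "-"),
    f("ATP8",  "protein",    8366,  8572, overlap = TRUE),
    f("ATP6",  "protein",    8527,  9207, overlap = TRUE),
    f("COX3",  "protein",    9207,  9990, incomplete = TRUE, overlap = TRUE),
    f("TRNG",  "tRNA",       9991, 10058),
    f("ND3",   "protein",   10059, 10404, incomplete = TRUE),
    f("TRNR",  "tRNA",      10405, 10469),
    f("ND4L",  "protein",   10470, 10766, overlap = TRUE),
    f("ND4",   "protein",   10760, 12137, incomplete = TRUE, overlap = TRUE),
    f("TRNH",  "tRNA",      12138, 12206),
    f("TRNS2", "tRNA",      12207, 12265),
    f("TRNL2", "tRNA",      12266, 12336),
    f("ND5",   "protein",   12337, 14148),
    f("ND6",   "protein",   14149, 14673, "L"),
    f("TRNE",  "tRNA",      14674, 14742, "L"),
    f("NC9",   "noncoding", 14743, 14746, "-"),
    f("CYB",   "protein",   14747, 15887, incomplete = TRUE),
    f("TRNT",  "tRNA",      15888, 15953),
    f("NC10",  "noncoding", 15954, 15955, "-"),
    f("TRNP",  "tRNA",      15956, 16023, "L"),
    f("CR",    "noncoding", 16024, 16569, "-"))
}

# codons engineered so that the printed variants have their printed effects,
# e.g. ND5 codon 361 = GGA so G13417A creates the AGA stop (G361TERM) and the
# 360-residue truncation, COX1 codon 193 = GTA so T6481C encodes V193A.
engineered_codons <- list(
  ND2  = c("302" = "GGC", "346" = "ATT"),
  COX1 = c("193" = "GTA"),
  ATP6 = c("15" = "CTA", "16" = "ACC", "179" = "CTA", "218" = "GTA"),
  ND3  = c("68" = "CTA", "115" = "GAA"),
  ND4L = c("59" = "GTA"),
  ND4  = c("2" = "CTA", "3" = "ACC", "372" = "ACT", "416" = "TGG"),
  ND5  = c("361" = "GGA", "385" = "TTC", "399" = "GCC", "442" = "AAC",
           "592" = "TTC"),
  ND6  = c("74" = "GCC", "88" = "GTC", "117" = "AAT"))

# fixed bases in non-protein regions: the 302-315 blacklist motif printed in
# the source data, the NC5 5-C homopolymer ending at 5899, reference alleles
# for the tabulated tRNA/rRNA/non-coding variants, and a short A-run across
# the origin junction.
engineered_bases <- function() {
  v <- c("150" = "C", "152" = "T", "529" = "G", "960" = "C", "1642" = "G",
         "2553" = "G", "4308" = "G", "5560" = "G", "5753" = "G",
         "5894" = "A", "5900" = "T", "10411" = "A", "12308" = "A",
         "15995" = "G",
         "16192" = "C", "16270" = "T", "16327" = "C",
         "16567" = "C", "16568" = "A", "16569" = "A",
         "1" = "A", "2" = "A", "3" = "T")
  black <- strsplit("ACCCCCCCTCCCCC", "")[[1L]]
  names(black) <- as.character(302:315)
  run <- rep("C", 5L); names(run) <- as.character(5895:5899)
  c(v, black, run)
}

sense_codons <- function() {
  all64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                 paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all64, MITO_STOPS)
}

# assemble one H-strand CDS: ATG + sampled sense codons with engineered
# overrides (+ stop codon when `stop` given); returns the codon vector
build_cds_codons <- function(n_codons, constraints, stop = NULL) {
  sense <- sense_codons()
  codons <- sample(sense, n_codons, replace = TRUE)
  codons[1L] <- "ATG"
  if (!is.null(stop)) codons[n_codons] <- stop
  for (idx in names(constraints)) codons[as.integer(idx)] <- constraints[[idx]]
  codons
}

codons_ok_in_frame <- function(seq_chars, starts) {
  codons <- paste0(seq_chars[starts], seq_chars[starts + 1L],
                   seq_chars[starts + 2L])
  !any(codons %in% MITO_STOPS)
}

#' Synthesize the bundled reference sequence
#'
#' Builds the synthetic rCRS-like genome deterministically: random filler
#' bases under `seed`, authentic gene architecture, and engineered codons at
#' the positions used by the worked examples. Dicistronic overlaps (ATP8/ATP6,
#' ND4L/ND4, the shared ATP6/COX3 base) are constructed so both reading frames
#' are stop-free, as in the real genome.
#'
#' @param seed Integer seed fixing the filler bases.
#' @return list with elements `sequence` (character scalar, 16,569 bp) and
#'   `features` (the gene-coordinate table).
#' @export
synthesize_reference <- function(seed = 12920) {
  set.seed(seed)
  L <- 16569L
  feats <- mito_feature_table()
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  put_codons <- function(s, start, codons) {
    chars <- strsplit(paste(codons, collapse = ""), "")[[1L]]
    s[start:(start + length(chars) - 1L)] <- chars
    s
  }

  # plain H-strand genes (full stop or incomplete trailing base(s))
  s <- put_codons(s, 3307L, build_cds_codons(318L, NULL))           # ND1
  s[4261:4262] <- c("T", "A")
  s <- put_codons(s, 4470L, build_cds_codons(347L, engineered_codons$ND2))
  s[5511L] <- "T"                                                   # ND2
  s <- put_codons(s, 5904L,
                  build_cds_codons(514L, engineered_codons$COX1, "AGA"))
  s <- put_codons(s, 7586L, build_cds_codons(228L, NULL, "TAG"))    # COX2

  # ATP6 with its start at 8527 inside ATP8; codons 2..14 re-sampled until the
  # shifted ATP8 frame (codon starts 8525, 8528, ...) is also stop-free.
  # Codons 15/16 are pinned ("CTA", "ACC") so the ATP8 stop TAA lands at
  # 8570..8572, and the terminal TAA shares its last base with the COX3 ATG.
  repeat {
    atp6 <- build_cds_codons(227L, engineered_codons$ATP6, "TAA")
    cand <- s
    cand <- put_codons(cand, 8527L, atp6)
    cand[8525:8526] <- c("C", "C")  # ATP8 codon 54 = CCA
    if (codons_ok_in_frame(cand, seq(8525L, 8567L, 3L))) { s <- cand; break }
  }
  s <- put_codons(s, 8366L, build_cds_codons(53L, NULL))            # ATP8 1..53
  stopifnot(paste0(s[8570L], s[8571L], s[8572L]) == "TAA")
  s <- put_codons(s, 9207L, build_cds_codons(261L, NULL))           # COX3
  s[9990L] <- "T"
  stopifnot(paste0(s[9205L], s[9206L], s[9207L]) == "TAA")

  s <- put_codons(s, 10059L, build_cds_codons(115L, engineered_codons$ND3))
  s[10404L] <- "T"                                                  # ND3

  # ND4 first (codons 2..3 pinned so the ND4L stop TAA lands at 10764..10766),
  # then ND4L codons 1..96 plus pinned codon 97 = CCA around the shared ATG.
  s <- put_codons(s, 10760L, build_cds_codons(459L, engineered_codons$ND4))
  s[12137L] <- "T"
  s <- put_codons(s, 10470L, build_cds_codons(96L, NULL))
  s[10758:10759] <- c("C", "C")
  stopifnot(paste0(s[10764L], s[10765L], s[10766L]) == "TAA",
            codons_ok_in_frame(s, seq(10470L, 10761L, 3L)))

  s <- put_codons(s, 12337L,
                  build_cds_codons(604L, engineered_codons$ND5, "TAA"))
  s <- put_codons(s, 14747L, build_cds_codons(380L, NULL))          # CYB
  s[15887L] <- "T"

  # ND6 is L-strand encoded: build its CDS, write the reverse complement
  nd6 <- build_cds_codons(175L, engineered_codons$ND6, "AGG")
  nd6_seq <- strsplit(revcomp(paste(nd6, collapse = "")), "")[[1L]]
  s[14149:14673] <- nd6_seq

  # non-protein fixed bases last (none fall inside protein genes)
  eb <- engineered_bases()
  s[as.integer(names(eb))] <- unname(eb)

  list(sequence = paste(s, collapse = ""), features = feats)
}

#' Write the synthetic reference fixture files
#'
#' Writes `synthetic_rCRS.fasta` and `synthetic_rCRS_features.tsv` (the files
#' bundled under `inst/extdata/`) into `dir`.
#'
#' @param dir Output directory.
#' @param seed Passed to [synthesize_reference()].
#' @return Invisibly, the two file paths.
#' @export
write_reference_fixture <- function(dir, seed = 12920) {
  ref <- synthesize_reference(seed)
  fa <- file.path(dir, "synthetic_rCRS.fasta")
  tsv <- file.path(dir, "synthetic_rCRS_features.tsv")
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- "NC_012920.1-synthetic 16569 bp synthetic rCRS-like construct"
  Biostrings::writeXStringSet(dna, fa, width = 70L)
  utils::write.table(ref$features, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, tsv))
}

#' Synthetic LINE/SINE repeat decoy library
#'
#' Fixed pseudo-random sequences standing in for nuclear repeat elements: one
#' LINE-like 2 kb element and two SINE-like ~300 bp elements. Reads mapping to
#' these decoys can only originate from nuclear DNA, which is what makes them
#' usable for contamination estimation.
#'
#' @param seed Integer seed (fixed default so the library is stable).
#' @return Named character vector of decoy sequences.
#' @export
synthetic_repeat_library <- function(seed = 77261) {
  set.seed(seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  c(LINE1_syn = rand_seq(2000L),
    ALU_syn_a = rand_seq(300L),
    ALU_syn_b = rand_seq(310L))
}
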