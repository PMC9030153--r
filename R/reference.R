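MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Vertebrate mitochondrial genetic code
#'
#' Codon table used for all translation in this package. In the vertebrate
#' mitochondrial code AGA and AGG are stop codons, ATA codes for Met and TGA
#' codes for Trp, all of which differ from the standard nuclear code.
#'
#' @return Named character vector mapping each of the 64 codons to a one-letter
#'   amino acid, with `"*"` for stop.
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")  # SGC1, vertebrate mitochondrial
  stopifnot(all(code[MITO_STOPS] == "*"), code[["ATA"]] == "M",
            code[["TGA"]] == "W")
  code
}

#' Load a circular mitochondrial reference genome
#'
#' Reads a single-record FASTA and a tab-separated gene-coordinate table into
#' a validated circular reference object. Coordinates are 1-based inclusive on
#' the L-strand, the convention in which mitochondrial variants are written
#' (T6481C means position 6481). Features that wrap the origin (the control
#' region) are stored as two segments sharing one name.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param feature_table_path Path to a TSV with columns `name`, `kind`
#'   (`protein`/`tRNA`/`rRNA`/`noncoding`), `start`, `end`, `strand` (`H`/`L`),
#'   `frame`, `incomplete_stop`, `overlap_ok`.
#' @return An object of class `mito_reference`: a list with elements `name`,
#'   `sequence` (uppercase character scalar), `length`, `features`
#'   (data.frame) and `code` (the vertebrate mitochondrial codon table).
#' @export
load_reference <- function(fasta_path, feature_table_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(dna))
  sequence <- toupper(as.character(dna[[1L]]))
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence contains characters other than A/C/G/T/N")

  feats <- utils::read.delim(feature_table_path, stringsAsFactors = FALSE)
  required <- c("name", "kind", "start", "end", "strand", "frame",
                "incomplete_stop", "overlap_ok")
  if (!all(required %in% names(feats)))
    stop("feature table must have columns: ", paste(required, collapse = ", "))
  feats$incomplete_stop <- as.logical(feats$incomplete_stop)
  feats$overlap_ok <- as.logical(feats$overlap_ok)

  ref <- structure(
    list(name = sub(" .*", "", names(dna)[1L]),
         sequence = sequence,
         length = nchar(sequence),
         features = feats[order(feats$start), , drop = FALSE],
         code = mito_genetic_code()),
    class = "mito_reference")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  feats <- ref$features
  L <- ref$length
  if (any(feats$start < 1L) || any(feats$end > L) ||
      any(feats$start > feats$end))
    stop("feature coordinates outside 1..", L,
         " (wrapping features must be stored as two segments)")
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(feats)))
    covered[feats$start[i]:feats$end[i]] <- TRUE
  if (!all(covered))
    stop("feature table does not span the sequence: position ",
         which(!covered)[1L], " uncovered")
  prot <- feats[feats$kind == "protein", , drop = FALSE]
  len <- prot$end - prot$start + 1L
  bad <- len %% 3L != 0L & !prot$incomplete_stop
  if (any(bad))
    stop("protein feature length not divisible by 3 without an ",
         "incomplete-stop flag: ", paste(prot$name[bad], collapse = ", "))
  # overlapping protein features (ATP8/ATP6 style) need an explicit flag
  if (nrow(prot) > 1L) {
    for (i in seq_len(nrow(prot) - 1L)) for (j in (i + 1L):nrow(prot)) {
      if (prot$start[j] <= prot$end[i] && prot$end[j] >= prot$start[i] &&
          !(prot$overlap_ok[i] && prot$overlap_ok[j]))
        stop("overlapping protein features without overlap flag: ",
             prot$name[i], "/", prot$name[j])
    }
  }
  invisible(ref)
}

#' Bundled synthetic rCRS-like reference
#'
#' Loads the reference bundled with the package. The sequence is a *synthetic*
#' construct (see [synthesize_reference()]): it has the authentic rCRS length
#' of 16,569 bp, the authentic 37-gene map and strand assignments of
#' NC_012920.1, and engineered codons at all positions used by the worked
#' examples, but random filler bases elsewhere. It is not the true human
#' sequence.
#'
#' @return A `mito_reference` object of length 16,569.
#' @export
mito_reference <- function() {
  load_reference(
    system.file("extdata", "synthetic_rCRS.fasta", package = "mseekr",
                mustWork = TRUE),
    system.file("extdata", "synthetic_rCRS_features.tsv", package = "mseekr",
                mustWork = TRUE))
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, ": ", x$length, " bp (circular), ",
      nrow(x$features), " feature segments\n", sep = "")
  invisible(x)
}

# circular position normalization: maps any integer onto 1..L
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

#' Circular base access
#'
#' @param ref A `mito_reference`.
#' @param pos Integer vector of positions; values outside 1..L wrap around the
#'   origin, so position L + 1 is position 1.
#' @return Character vector of single bases.
#' @export
ref_base <- function(ref, pos) {
  p <- wrap_pos(as.integer(pos), ref$length)
  substring(ref$sequence, p, p)
}

#' Extract a circular segment of the reference
#'
#' @param ref A `mito_reference`.
#' @param start 1-based start position.
#' @param len Segment length; segments extending past position L wrap to 1.
#' @return Character scalar of length `len`.
#' @export
ref_segment <- function(ref, start, len) {
  L <- ref$length
  start <- wrap_pos(as.integer(start), L)
  if (len <= L - start + 1L) return(substring(ref$sequence, start, start + len - 1L))
  paste0(substring(ref$sequence, start, L),
         ref_segment(ref, 1L, len - (L - start + 1L)))
}

#' Features overlapping a position
#'
#' Every position of the genome belongs to at least one feature (intergenic
#' stretches are named non-coding features), so the result is never empty.
#'
#' @param ref A `mito_reference`.
#' @param pos A single 1-based position in 1..L.
#' @return The rows of `ref$features` whose interval contains `pos`,
#'   ordered by start.
#' @export
locate_features <- function(ref, pos) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > ref$length)
    stop("position must be a single value in 1..", ref$length)
  f <- ref$features
  hits <- f[f$start <= pos & f$end >= pos, , drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

get_feature <- function(ref, gene) {
  if (is.data.frame(gene)) return(gene)
  f <- ref$features[ref$features$name == gene, , drop = FALSE]
  if (nrow(f) == 0L) stop("no feature named ", gene)
  f
}

# coding sequence of a protein gene in reading orientation, trailing partial
# codon (incomplete stop, completed by polyadenylation) dropped
gene_cds <- function(ref, feat) {
  seg <- substring(ref$sequence, feat$start, feat$end)
  if (feat$strand == "L") seg <- revcomp(seg)
  n_full <- (nchar(seg) %/% 3L) * 3L
  substring(seg, 1L, n_full)
}

#' Translate a protein-coding mitochondrial gene
#'
#' Translates under the vertebrate mitochondrial code up to and excluding the
#' first stop codon. Genes encoded on the H strand (e.g. ND6) are translated
#' from the reverse complement of the L-strand reference. For genes with an
#' incomplete stop codon (completed post-transcriptionally by polyadenylation)
#' the trailing partial codon is ignored.
#'
#' @param ref A `mito_reference`.
#' @param gene Gene name (e.g. `"ND5"`) or a feature row.
#' @return Amino-acid string of the translated protein.
#' @export
translate_mito <- function(ref, gene) {
  feat <- get_feature(ref, gene)
  if (feat$kind[1L] != "protein")
    stop(feat$name[1L], " is not a protein-coding gene")
  cds <- gene_cds(ref, feat[1L, ])
  if (grepl("N", cds)) stop("internal N bases in ", feat$name[1L])
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- unname(ref$code[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Parse a variant label in mitochondrial notation
#'
#' Substitutions are written reference-position-alternate (`"T6481C"`);
#' insertions repeat the reference base followed by the inserted bases
#' (`"C5899CC"` is one C inserted after position 5899); deletions list the
#' deleted reference bases on the left (`"CA5899C"`).
#'
#' @param label Character vector of variant labels.
#' @return data.frame with columns `label`, `position`, `ref`, `alt`, `style`.
#' @export
parse_variant <- function(label) {
  m <- regmatches(label, regexec("^([ACGTN]+)([0-9]+)([ACGTN]+)$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed variant label: ", label[bad][1L])
  ref <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  style <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "substitution",
           ifelse(nchar(alt) > nchar(ref) & startsWith(alt, ref), "insertion",
           ifelse(nchar(ref) > nchar(alt) & startsWith(ref, alt), "deletion",
                  NA_character_)))
  if (anyNA(style)) stop("unsupported variant style: ", label[is.na(style)][1L])
  if (any(style == "substitution" & ref == alt))
    stop("substitution with identical ref and alt: ",
         label[style == "substitution" & ref == alt][1L])
  data.frame(label = label, position = pos, ref = ref, alt = alt,
             style = style, stringsAsFactors = FALSE)
}

#' Mutation-spectrum class of a variant on the L strand
#'
#' Substitutions fall into the 12 L-strand classes (`"T>C"`, `"G>A"`, ...);
#' insertions and deletions are their own classes. Spectrum classes are always
#' reported in L-strand orientation regardless of the strand of any gene the
#' variant falls in, the convention in which mitochondrial mutation spectra
#' are tabulated.
#'
#' @param ref_allele,alt_allele Single reference/alternate bases (or allele
#'   strings for indels).
#' @param style `"substitution"`, `"insertion"` or `"deletion"`.
#' @return Character vector of class labels.
#' @export
spectrum_class <- function(ref_allele, alt_allele,
                           style = "substitution") {
  n <- max(length(ref_allele), length(alt_allele), length(style))
  style <- rep_len(style, n)
  ifelse(style == "substitution",
         paste0(rep_len(ref_allele, n), ">", rep_len(alt_allele, n)), style)
}

#' Transition test
#'
#' @param class Spectrum class labels from [spectrum_class()].
#' @return Logical: `TRUE` for the four transition classes
#'   (A>G, G>A, C>T, T>C).
#' @export
is_transition <- function(class) class %in% c("A>G", "G>A", "C>T", "T>C")

#' Apply substitution variants to a reference
#'
#' Returns a copy of the reference with the given substitutions applied.
#' Insertions and deletions change coordinates and are deliberately not
#' supported at the reference level; apply those on molecule sequences via the
#' simulator instead.
#'
#' @param ref A `mito_reference`.
#' @param variants Variant labels or a data.frame from [parse_variant()].
#' @return A modified `mito_reference`.
#' @export
apply_substitutions <- function(ref, variants) {
  v <- if (is.character(variants)) parse_variant(variants) else variants
  if (any(v$style != "substitution"))
    stop("only substitutions can be applied to the reference in place")
  seq <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  mismatch <- seq[v$position] != v$ref
  if (any(mismatch))
    stop("reference allele mismatch at position ", v$position[mismatch][1L],
         ": expected ", v$ref[mismatch][1L], ", found ",
         seq[v$position[mismatch]][1L])
  seq[v$position] <- v$alt
  ref$sequence <- paste(seq, collapse = "")
  ref
}

annotate_in_feature <- function(ref, v, feat) {
  cons <- NA_character_
  aa_change <- NA_character_
  codon_change <- NA_character_
  trunc_len <- NA_integer_
  if (feat$kind == "protein" && v$style == "substitution") {
    if (feat$strand == "H") {
      offset <- v$position - feat$start
      alt_base <- v$alt
    } else {
      offset <- feat$end - v$position
      alt_base <- comp_base(v$alt)
    }
    codon_index <- offset %/% 3L + 1L
    pos_in_codon <- offset %% 3L + 1L
    cds <- gene_cds(ref, feat)
    n_codons <- nchar(cds) %/% 3L
    if (codon_index > n_codons) {
      cons <- "noncoding"  # trailing partial (incomplete-stop) codon
    } else {
      codon <- substring(cds, 3L * codon_index - 2L, 3L * codon_index)
      alt_codon <- codon
      substring(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
      aa_ref <- unname(ref$code[codon])
      aa_alt <- unname(ref$code[alt_codon])
      codon_change <- paste0(codon, ">", alt_codon)
      if (aa_alt == "*" && aa_ref != "*") {
        cons <- "nonsense"
        aa_change <- paste0(aa_ref, codon_index, "TERM")
        trunc_len <- codon_index - 1L
      } else if (aa_ref == aa_alt) {
        cons <- "synonymous"
        aa_change <- paste0(aa_ref, codon_index, aa_alt)
      } else {
        cons <- "missense"
        aa_change <- paste0(aa_ref, codon_index, aa_alt)
      }
    }
  } else if (feat$kind == "protein") {
    cons <- "frameshift-insertion"
    if (v$style == "deletion") cons <- "frameshift-deletion"
  } else if (feat$kind == "tRNA") {
    cons <- "tRNA"
  } else if (feat$kind == "rRNA") {
    cons <- "rRNA"
  } else {
    cons <- "noncoding"
  }
  cls <- spectrum_class(v$ref, v$alt, v$style)
  data.frame(label = v$label, position = v$position, feature = feat$name,
             kind = feat$kind, consequence = cons, codon_change = codon_change,
             aa_change = aa_change, truncated_length = trunc_len,
             spectrum_class = cls, transition = is_transition(cls),
             stringsAsFactors = FALSE)
}

#' Annotate the consequence of a variant
#'
#' Reports, for every feature overlapping the variant position, the gene,
#' consequence (synonymous / missense / nonsense / tRNA / rRNA / noncoding /
#' frameshift-insertion), amino-acid change in compact notation (`V193A`,
#' `G361TERM`), L-strand spectrum class and transition flag. For nonsense
#' substitutions the length of the truncated protein is reported.
#'
#' @param ref A `mito_reference`.
#' @param variant A single variant label (e.g. `"T6481C"`) or one row from
#'   [parse_variant()].
#' @return data.frame with one row per overlapping feature.
#' @export
consequence_of <- function(ref, variant) {
  v <- if (is.character(variant)) parse_variant(variant) else variant
  if (nrow(v) != 1L) stop("annotate one variant at a time")
  found <- ref_segment(ref, v$position, nchar(v$ref))
  if (found != v$ref)
    stop("reference allele mismatch at ", v$position, ": label says ", v$ref,
         ", reference has ", found)
  feats <- locate_features(ref, v$position)
  out <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i)
    annotate_in_feature(ref, v, feats[i, , drop = FALSE])))
  rownames(out) <- NULL
  out
}

#' Homopolymer run through a position
#'
#' Length and base of the maximal single-base run containing `pos` on the
#' L strand, counted across the origin junction (the genome is circular).
#' Homopolymer context matters because replication slippage within such runs
#' is the usual source of single-base insertions.
#'
#' @param ref A `mito_reference`.
#' @param pos A single position in 1..L.
#' @return list with elements `length` and `base`.
#' @export
homopolymer_run <- function(ref, pos) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || pos < 1L || pos > ref$length)
    stop("position must be a single value in 1..", ref$length)
  base <- ref_base(ref, pos)
  len <- 1L
  i <- pos - 1L
  while (len < ref$length && ref_base(ref, i) == base) {
    len <- len + 1L; i <- i - 1L
  }
  i <- pos + 1L
  while (len < ref$length && ref_base(ref, i) == base) {
    len <- len + 1L; i <- i + 1L
  }
  list(length = len, base = base)
}
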