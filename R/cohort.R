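# Cohort-level summaries: heteroplasmy arithmetic, read-count filters for
# tabulated reanalysis, L-strand mutation-spectrum tables, pooled summaries
# and functional-category tallies.

# printed percents use round-half-up (62.5% prints as 63%), unlike R's
# round-half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percent heteroplasmy from read counts
#'
#' `(variant read count / (variant read count + WT read count)) x 100`.
#'
#' @param variant_reads,wt_reads Non-negative read counts; their sum must be
#'   positive.
#' @return Percent heteroplasmy in \[0, 100\].
#' @export
heteroplasmy_percent <- function(variant_reads, wt_reads) {
  if (any(variant_reads < 0) || any(wt_reads < 0))
    stop("read counts must be non-negative")
  total <- variant_reads + wt_reads
  if (any(total == 0)) stop("zero total read count")
  100 * variant_reads / total
}

#' Read-count filter for tabulated tumor/normal variant records
#'
#' A record is retained iff the tumor sample has read counts above the cutoff
#' (variant *or* WT, i.e. `max(tumor variant, tumor WT) > count_cutoff`), the
#' matched normal WT count exceeds the cutoff, and residual heteroplasmy in
#' the matched normal is below `normal_het_cutoff` percent.
#'
#' @param records data.frame with columns `tumor_variant_reads`,
#'   `tumor_wt_reads`, `normal_variant_reads`, `normal_wt_reads`.
#' @param count_cutoff Read-count cutoff (default 100).
#' @param normal_het_cutoff Maximum residual normal heteroplasmy, percent
#'   (default 0.4).
#' @param require_both If `TRUE`, require both tumor counts above the cutoff
#'   instead of either.
#' @return The retained rows of `records`.
#' @export
ju_filter <- function(records, count_cutoff = 100, normal_het_cutoff = 0.4,
                      require_both = FALSE) {
  tumor_ok <- if (require_both)
    pmin(records$tumor_variant_reads, records$tumor_wt_reads) > count_cutoff
  else
    pmax(records$tumor_variant_reads, records$tumor_wt_reads) > count_cutoff
  normal_total <- records$normal_variant_reads + records$normal_wt_reads
  normal_het <- ifelse(normal_total > 0,
                       100 * records$normal_variant_reads / normal_total, 0)
  keep <- tumor_ok & records$normal_wt_reads > count_cutoff &
    normal_het < normal_het_cutoff
  records[keep, , drop = FALSE]
}

SPECTRUM_CLASSES <- as.vector(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"),
                                    function(a, b) paste0(a, ">", b)))
SPECTRUM_CLASSES <- SPECTRUM_CLASSES[substring(SPECTRUM_CLASSES, 1, 1) !=
                                     substring(SPECTRUM_CLASSES, 3, 3)]

record_classes <- function(records) {
  v <- parse_variant(records$variant)
  spectrum_class(v$ref, v$alt, v$style)
}

#' Mutation-spectrum table over the 12 L-strand substitution classes
#'
#' Substitutions are tallied in L-strand orientation (the reference strand in
#' which variants are written); insertions and deletions are tallied apart.
#' The transition percent uses all records (substitutions and indels) as the
#' denominator, the convention under which 8 transitions among 10 tumor
#' variants reads as 80%.
#'
#' @param records data.frame with a `variant` label column.
#' @return list: `spectrum` (named integer vector over the 12 classes),
#'   `insertions`, `deletions`, `transitions`, `transversions`,
#'   `substitutions`, `n`, `transition_percent` (round-half-up to integer).
#' @export
spectrum_table <- function(records) {
  if (nrow(records) == 0L) {
    sp <- stats::setNames(integer(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
    return(list(spectrum = sp, insertions = 0L, deletions = 0L,
                transitions = 0L, transversions = 0L, substitutions = 0L,
                n = 0L, transition_percent = NaN))
  }
  cls <- record_classes(records)
  subs <- cls[!cls %in% c("insertion", "deletion")]
  sp <- table(factor(subs, levels = SPECTRUM_CLASSES))
  sp <- stats::setNames(as.integer(sp), names(sp))
  n_ts <- sum(is_transition(subs))
  list(spectrum = sp,
       insertions = sum(cls == "insertion"),
       deletions = sum(cls == "deletion"),
       transitions = n_ts,
       transversions = length(subs) - n_ts,
       substitutions = length(subs),
       n = nrow(records),
       transition_percent = round_half_up(100 * n_ts / nrow(records)))
}

#' Pooled cohort summary
#'
#' Pools one or more cohorts of per-tumor variant records and reports tumor
#' and variant counts, the mean number of variants per tumor (one decimal),
#' and the number and percent of heteroplasmic variants under the
#' percent-variant threshold (92% by default; 100% is homoplasmy).
#'
#' @param cohorts A single data.frame or a list of data.frames, each with
#'   columns `tumor_id`, `variant`, `vaf`.
#' @param het_threshold Heteroplasmy threshold, percent (default 92).
#' @return list: `tumors`, `variants`, `mean_per_tumor` (1 decimal),
#'   `heteroplasmic`, `heteroplasmic_percent` (round-half-up integer).
#' @export
pooled_summary <- function(cohorts, het_threshold = 92) {
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  ids <- unlist(lapply(cohorts, function(x) unique(x$tumor_id)))
  if (anyDuplicated(ids))
    stop("tumor ids must be unique across cohorts: ",
         ids[duplicated(ids)][1L])
  all <- do.call(rbind, lapply(cohorts, function(x)
    x[, c("tumor_id", "variant", "vaf")]))
  n_het <- sum(all$vaf <= het_threshold)
  list(tumors = length(ids), variants = nrow(all),
       mean_per_tumor = round(nrow(all) / length(ids), 1),
       heteroplasmic = n_het,
       heteroplasmic_percent = round_half_up(100 * n_het / nrow(all)))
}

FUNCTIONAL_CATEGORIES <- c("missense", "tRNA", "noncoding", "nonsense",
                           "rRNA", "silent")

#' Tally variants by functional category
#'
#' Categories are mutually exclusive per variant and follow the primary
#' annotation: `missense`, `tRNA`, `noncoding` (control region, origins and
#' other non-coding features, including non-coding insertions), `nonsense`,
#' `rRNA`, and `silent` (synonymous).
#'
#' @param records data.frame with a `category` column (as in the bundled
#'   tables) or a `consequence` column from [consequence_of()].
#' @return Named integer vector over the six categories.
#' @export
functional_category_tally <- function(records) {
  cat_col <- if ("category" %in% names(records)) records$category
  else if ("consequence" %in% names(records)) {
    map <- c(missense = "missense", synonymous = "silent",
             nonsense = "nonsense", tRNA = "tRNA", rRNA = "rRNA",
             noncoding = "noncoding", `frameshift-insertion` = "noncoding")
    unname(map[records$consequence])
  } else stop("records need a 'category' or 'consequence' column")
  if (nrow(records) && anyNA(cat_col)) stop("unannotated record present")
  tab <- table(factor(cat_col, levels = FUNCTIONAL_CATEGORIES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Bundled endometrial-cancer tumor variant table
#'
#' The ten tumor-specific variants from three Mseek-sequenced endometrial
#' tumors (tumor ids P1-P3) with their printed percent heteroplasmy, per-site
#' coverage, gene and functional category.
#'
#' @return data.frame with columns `tumor_id`, `variant`, `gene`, `category`,
#'   `vaf`, `coverage`.
#' @export
ec_tumor_variants <- function() {
  utils::read.delim(system.file("extdata", "ec_tumor_variants.tsv",
                                package = "mseekr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Bundled uterine-tumor variant table (exome reanalysis)
#'
#' The sixteen uterine-tumor mtDNA variants retained by the read-count
#' filters in the tabulated reanalysis of a published pan-cancer dataset, one
#' row per variant with sample index and percent heteroplasmy.
#'
#' @return data.frame with columns `tumor_id`, `variant`, `gene`, `category`,
#'   `vaf`.
#' @export
ju_uterine_variants <- function() {
  utils::read.delim(system.file("extdata", "ju_uterine_variants.tsv",
                                package = "mseekr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
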