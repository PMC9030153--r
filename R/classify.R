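# Somatic vs germline classification of matched peri-normal/tumor call sets
# against a haplogroup variant-frequency table.

#' Load a haplogroup variant-frequency table
#'
#' A haplogroup branch is the collection of mtDNA alleles inherited together;
#' a variant present in the branch table (at any frequency) is taken as part
#' of the inherited background. Tables are user-supplied TSVs with columns
#' `variant` (label) and `frequency` (percent in the branch, in (0, 100]).
#'
#' @param path TSV file path.
#' @param branch Optional branch name carried in the result.
#' @return list of class `haplogroup_table`: `branch`, `frequencies`
#'   (named numeric vector, percent by variant label).
#' @export
load_haplogroup_table <- function(path, branch = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "frequency") %in% names(tab)))
    stop("haplogroup table needs columns 'variant' and 'frequency'")
  if (anyDuplicated(tab$variant))
    stop("duplicate variant labels in haplogroup table: ",
         tab$variant[duplicated(tab$variant)][1L])
  if (any(!is.finite(tab$frequency)) ||
      any(tab$frequency <= 0 | tab$frequency > 100))
    stop("haplogroup frequencies must lie in (0, 100]")
  freqs <- stats::setNames(tab$frequency, tab$variant)
  structure(list(branch = branch, frequencies = freqs),
            class = "haplogroup_table")
}

#' An empty haplogroup table
#'
#' With no branch information every shared variant classifies as
#' shared-but-possibly-acquired.
#'
#' @return A `haplogroup_table` with no entries.
#' @export
empty_haplogroup_table <- function() {
  structure(list(branch = NA_character_,
                 frequencies = stats::setNames(numeric(), character())),
            class = "haplogroup_table")
}

#' Heteroplasmy status of a percent-variant value
#'
#' Heteroplasmic when at most 92% of reads carry the variant; nearly
#' homoplasmic from 93% up to (but excluding) 100%; homoplasmic at 100%
#' (all molecules carry the allele).
#'
#' @param percent_variant Percent in (0, 100].
#' @return Character vector: `"heteroplasmic"`, `"near_homoplasmic"` or
#'   `"homoplasmic"`.
#' @export
heteroplasmy_status <- function(percent_variant) {
  if (any(!is.finite(percent_variant)) ||
      any(percent_variant <= 0 | percent_variant > 100))
    stop("percent_variant must lie in (0, 100]")
  ifelse(percent_variant >= 100, "homoplasmic",
         ifelse(percent_variant <= 92, "heteroplasmic", "near_homoplasmic"))
}

#' Classify variant calls from a matched normal/tumor pair
#'
#' Only PASS calls count as "present"; blacklisted calls are never
#' classified. The operational rules: a variant present in the tumor but
#' absent from the matched peri-normal sample is **somatic**; present in both
#' and listed in the haplogroup table, **germline** (inherited); present in
#' both but absent from the haplogroup, **shared_possibly_acquired** (it may
#' not have been inherited); present only in the normal sample,
#' **normal_specific**. Heteroplasmy status is labeled from the tumor
#' percent-variant when the variant is in the tumor, otherwise from the
#' normal value.
#'
#' @param normal_calls,tumor_calls `variant_calls` data.frames from
#'   [call_variants()] against the same reference.
#' @param table A `haplogroup_table`.
#' @param vaf_field Which percent-variant field to carry (`"vaf_plus"`,
#'   the plus-strand convention, or `"vaf_both"`).
#' @param min_somatic_vaf Optional floor (percent) on tumor percent-variant
#'   for somatic labels; `NULL` (default) applies none.
#' @return data.frame: `label`, `classification`, `status`, `normal_vaf`,
#'   `tumor_vaf`, `haplogroup_frequency`.
#' @export
classify_pair <- function(normal_calls, tumor_calls, table = empty_haplogroup_table(),
                          vaf_field = c("vaf_plus", "vaf_both"),
                          min_somatic_vaf = NULL) {
  vaf_field <- match.arg(vaf_field)
  n_pass <- normal_calls[normal_calls$filter == "PASS", , drop = FALSE]
  t_pass <- tumor_calls[tumor_calls$filter == "PASS", , drop = FALSE]
  labels <- union(t_pass$label, n_pass$label)
  if (!length(labels))
    return(data.frame(label = character(), classification = character(),
                      status = character(), normal_vaf = numeric(),
                      tumor_vaf = numeric(), haplogroup_frequency = numeric(),
                      stringsAsFactors = FALSE))
  in_n <- labels %in% n_pass$label
  in_t <- labels %in% t_pass$label
  in_h <- labels %in% names(table$frequencies)
  cls <- ifelse(in_t & !in_n, "somatic",
         ifelse(in_t & in_n & in_h, "germline",
         ifelse(in_t & in_n, "shared_possibly_acquired", "normal_specific")))
  nv <- n_pass[[vaf_field]][match(labels, n_pass$label)]
  # audit value: the (possibly sub-threshold) normal signal for tumor calls
  nv_any <- normal_calls[[vaf_field]][match(labels, normal_calls$label)]
  nv <- ifelse(is.na(nv), nv_any, nv)
  tv <- t_pass[[vaf_field]][match(labels, t_pass$label)]
  if (!is.null(min_somatic_vaf))
    cls[cls == "somatic" & tv < min_somatic_vaf] <- "somatic_below_floor"
  status_vaf <- ifelse(in_t, tv, nv)
  status <- rep(NA_character_, length(labels))
  ok <- is.finite(status_vaf) & status_vaf > 0
  status[ok] <- heteroplasmy_status(pmin(status_vaf[ok], 100))
  out <- data.frame(
    label = labels, classification = cls, status = status,
    normal_vaf = nv, tumor_vaf = tv,
    haplogroup_frequency = unname(table$frequencies[labels]),
    stringsAsFactors = FALSE)
  out <- out[order(parse_variant(out$label)$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
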