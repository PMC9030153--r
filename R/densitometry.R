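# Quantitation of 1-D Southern-blot lane intensity profiles: band
# integration, dual-probe copy-number ratios, lane-loading statistics and
# catenane-region comparisons.

profile_lane <- function(profiles, lane) {
  p <- profiles[profiles$lane == lane, , drop = FALSE]
  if (nrow(p) == 0L) stop("no profile for lane ", lane)
  if (any(diff(p$position) <= 0)) stop("positions must be strictly increasing")
  if (any(p$intensity < 0)) stop("negative intensities")
  p
}

#' Integrate a band window of a lane profile
#'
#' Trapezoidal integral of intensity over the window, minus an optional
#' linear baseline drawn between the window's endpoints (the usual manual
#' background correction in gel densitometry). Negative background-corrected
#' integrals are clamped to zero.
#'
#' @param profiles data.frame (`lane`, `position`, `intensity`).
#' @param lane Lane id.
#' @param window `c(lo, hi)` positions within the profile range.
#' @param background `"none"` or `"linear-baseline"`.
#' @return list of class `band_quant`: `lane`, `window`, `signal`,
#'   `background`.
#' @export
integrate_band <- function(profiles, lane, window,
                           background = c("none", "linear-baseline")) {
  background <- match.arg(background)
  p <- profile_lane(profiles, lane)
  sel <- p$position >= window[1] & p$position <= window[2]
  if (sum(sel) < 2L) stop("empty band window")
  x <- p$position[sel]; y <- p$intensity[sel]
  area <- pracma::trapz(x, y)
  if (background == "linear-baseline") {
    base <- y[1L] + (y[length(y)] - y[1L]) * (x - x[1L]) / (x[length(x)] - x[1L])
    area <- max(0, area - pracma::trapz(x, base))
  }
  structure(list(lane = lane, window = window, signal = area,
                 background = background), class = "band_quant")
}

#' mtDNA/nDNA copy-number ratios normalized to a reference lane
#'
#' Each lane's ratio of mtDNA band signal to nuclear (18S) band signal is
#' expressed as a percent of the reference lane's ratio (the reference lane
#' reports 100).
#'
#' @param quants data.frame with columns `lane`, `mtdna`, `ndna` (integrated
#'   band signals per lane).
#' @param reference_lane Lane id set to 100%.
#' @return data.frame `lane`, `ratio`, `percent_of_reference`.
#' @export
copy_number_ratio <- function(quants, reference_lane) {
  if (!reference_lane %in% quants$lane) stop("reference lane not present")
  if (any(quants$ndna <= 0)) stop("zero nuclear-band signal")
  ratio <- quants$mtdna / quants$ndna
  ref <- ratio[match(reference_lane, quants$lane)]
  data.frame(lane = quants$lane, ratio = ratio,
             percent_of_reference = 100 * ratio / ref)
}

#' Lane-loading statistics
#'
#' Whole-lane signals expressed as a percent of the total over all lanes,
#' with their mean and percent coefficient of variation (100 x sd / mean);
#' equal loading gives equal percents and a %CV near zero.
#'
#' @param signals Numeric vector of whole-lane integrated signals (>= 2
#'   lanes, not all zero).
#' @return list: `percent` (sums to 100), `mean_percent`, `cv_percent`.
#' @export
lane_load_stats <- function(signals) {
  if (length(signals) < 2L) stop("need at least 2 lanes")
  if (all(signals == 0)) stop("all lanes are zero")
  pct <- 100 * signals / sum(signals)
  list(percent = pct, mean_percent = mean(pct),
       cv_percent = 100 * stats::sd(pct) / mean(pct))
}

#' Catenane fraction per lane and normal/tumor group comparison
#'
#' For each lane, the catenane-region signal is quantitated as a percent of
#' the whole-lane signal. Lanes are grouped by their label; the fold change
#' is mean(tumor)/mean(normal) and the group difference is assessed with a
#' two-sided equal-variance two-sample t-test.
#'
#' @param profiles data.frame (`lane`, `position`, `intensity`).
#' @param lanes data.frame with columns `lane`, `group` (`"normal"` or
#'   `"tumor"`), `cat_lo`, `cat_hi` (catenane window per lane; the window is
#'   user input, mirroring manual region selection on a blot).
#' @return list: `per_lane` (lane, group, catenane percent), `fold_change`,
#'   `p_value` (`NA` unless both groups have >= 2 lanes).
#' @export
catenane_fraction <- function(profiles, lanes) {
  if (!all(c("lane", "group", "cat_lo", "cat_hi") %in% names(lanes)))
    stop("lanes needs columns lane, group, cat_lo, cat_hi")
  if (!all(lanes$group %in% c("normal", "tumor")))
    stop("groups must be 'normal' or 'tumor'")
  if (!all(c("normal", "tumor") %in% lanes$group))
    stop("both a normal and a tumor group are required")
  pct <- vapply(seq_len(nrow(lanes)), function(i) {
    p <- profile_lane(profiles, lanes$lane[i])
    whole <- pracma::trapz(p$position, p$intensity)
    if (whole == 0) stop("zero whole-lane signal in lane ", lanes$lane[i])
    cat_q <- integrate_band(profiles, lanes$lane[i],
                            c(lanes$cat_lo[i], lanes$cat_hi[i]))
    100 * cat_q$signal / whole
  }, 0)
  per_lane <- data.frame(lane = lanes$lane, group = lanes$group,
                         catenane_percent = pct)
  m_n <- mean(pct[lanes$group == "normal"])
  m_t <- mean(pct[lanes$group == "tumor"])
  p_value <- NA_real_
  if (sum(lanes$group == "normal") >= 2L && sum(lanes$group == "tumor") >= 2L &&
      stats::var(pct[lanes$group == "normal"]) +
      stats::var(pct[lanes$group == "tumor"]) > 0)
    p_value <- stats::t.test(pct[lanes$group == "tumor"],
                             pct[lanes$group == "normal"],
                             var.equal = TRUE)$p.value
  list(per_lane = per_lane, fold_change = m_t / m_n, p_value = p_value)
}
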