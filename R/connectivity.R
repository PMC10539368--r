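# Connectivity normalization: rabies-tracing index of connectivity (IOC)
# and CTB double-label percentages/densities.

#' Index of connectivity (IOC) per brain region
#'
#' `IOC = presynaptic neurons in region / starter neurons`, computed per
#' animal (and per hemisphere if a `hemisphere` column is present).
#' Doubling all counts and starters leaves the IOC unchanged.
#'
#' @param counts Tibble with columns `region`, `count`, `starter_count`
#'   and optionally `animal` / `hemisphere` grouping columns. Counts are
#'   assumed to already exclude starter neurons.
#' @return The input grouping columns plus `ioc`.
#' @export
compute_ioc <- function(counts) {
  req <- c("region", "count", "starter_count")
  if (!all(req %in% names(counts))) {
    abort("`counts` needs columns region, count, starter_count.")
  }
  if (any(counts$count < 0)) abort("Presynaptic counts must be >= 0.")
  if (any(counts$starter_count < 1)) {
    abort("`starter_count` must be >= 1 (IOC undefined otherwise).")
  }
  out <- dplyr::mutate(as_tibble(counts), ioc = .data$count / .data$starter_count)
  class(out) <- c("bq_ioc", class(out))
  out
}

#' Ratio of two regions' IOC values
#'
#' E.g. the VPM/POm thalamic input ratio. With grouping columns present
#' the ratio is computed within each animal/hemisphere.
#'
#' @param ioc Output of [compute_ioc()].
#' @param numerator,denominator Region identifiers.
#' @return A tibble with any grouping columns plus `ratio` (`NA` with a
#'   warning where the denominator IOC is zero).
#' @export
ioc_ratio <- function(ioc, numerator, denominator) {
  if (!all(c(numerator, denominator) %in% ioc$region)) {
    abort("Both regions must be present in the IOC table.")
  }
  keys <- intersect(c("animal", "hemisphere"), names(ioc))
  wide <- tidyr::pivot_wider(
    dplyr::filter(ioc, .data$region %in% c(numerator, denominator)),
    id_cols = dplyr::all_of(keys),
    names_from = "region", values_from = "ioc"
  )
  den <- wide[[denominator]]
  if (any(den == 0, na.rm = TRUE)) {
    warn("Zero denominator IOC; ratio flagged NA.")
  }
  wide$ratio <- ifelse(den == 0, NA_real_, wide[[numerator]] / den)
  wide
}

#' CTB double-label percentage and labeling density
#'
#' Per section: `100 * double_positive / transfected` (the percentage of
#' retrogradely labeled CTB+GFP+ neurons among electroporated GFP+
#' neurons) and, where an ROI area is given, `labeled / area` (e.g. CTB+
#' density in L2/3).
#'
#' @param counts Tibble with per-section columns `double_positive` and
#'   `transfected`, optionally `labeled` and `area` for the density, plus
#'   any identifier columns (`animal`, `section`, `layer`, ...).
#' @return The input plus `percent` and (if applicable) `density`;
#'   sections with zero denominators are `NA` and flagged in `missing`.
#' @export
double_label_percent <- function(counts) {
  if (!all(c("double_positive", "transfected") %in% names(counts))) {
    abort("`counts` needs columns double_positive and transfected.")
  }
  if (any(counts$double_positive > counts$transfected, na.rm = TRUE)) {
    abort("double_positive cannot exceed transfected.")
  }
  out <- as_tibble(counts)
  out$missing <- out$transfected <= 0
  if (any(out$missing)) warn("Sections with zero transfected cells flagged.")
  out$percent <- ifelse(out$missing, NA_real_,
                        100 * out$double_positive / out$transfected)
  if (all(c("labeled", "area") %in% names(out))) {
    out$density <- ifelse(out$area > 0, out$labeled / out$area, NA_real_)
  }
  out
}
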