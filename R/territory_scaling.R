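# Cover-weighted upscaling of habitat-element biomass to territory-level
# prey availability over a fixed standardization area.

#' Standardized territory area
#'
#' Area of the circular buffer used to standardize territory-level biomass,
#' `pi * r^2`, rounded to the nearest square metre for reporting. The study
#' convention is a 100 m buffer around the occupied nest, giving 31,416 m2.
#'
#' @param radius_m Buffer radius in metres (> 0).
#' @return Area in m2 (rounded to nearest integer).
#' @export
standard_area <- function(radius_m = 100) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    stop_wrenlink("radius must be a positive number", "wrenlink_input_error")
  }
  round(pi * radius_m^2)
}

#' Upscale habitat-element biomass to territory availability
#'
#' For each territory, stratum and taxon, the availability is the
#' cover-weighted sum over habitat elements scaled to the standard area:
#' `sum_elements (percent_cover/100) * mean_biomass * area`. Elements with 0%
#' cover contribute zero; non-focal cover categories (e.g. `"other"`)
#' contribute zero biomass and their summed fraction is recorded in the
#' `nonfocal_cover` attribute. An element with positive cover in a territory
#' but no biomass estimate is a coverage-mismatch error.
#'
#' @param means Raw-scale cell table: columns `territory`, `habitat_element`,
#'   `stratum`, `taxon`, and `biomass_mg` (or `mean`), e.g. from
#'   [aggregate_cells()] or `marginal_means(..., transform = "raw")`.
#' @param cover Cover table: columns `territory`, `habitat_element`,
#'   `percent_cover`.
#' @param area_m2 Standardization area (default [standard_area()] at 100 m).
#' @param nonfocal Cover categories that carry no sampled biomass.
#' @return Long data.frame `territory`, `stratum`, `taxon`, `biomass_mg`
#'   (mg per standardized territory area), with attribute `nonfocal_cover`
#'   (named per-territory percent).
#' @export
upscale <- function(means, cover, area_m2 = standard_area(100),
                    nonfocal = c("other", "artificial")) {
  value_col <- if ("biomass_mg" %in% names(means)) "biomass_mg" else "mean"
  assert_columns(means, c("territory", "habitat_element", "stratum", "taxon",
                          value_col), "mean biomass table")
  assert_columns(cover, c("territory", "habitat_element", "percent_cover"),
                 "cover table")
  focal_cover <- cover[!cover$habitat_element %in% nonfocal, , drop = FALSE]
  nonfocal_cover <- tapply(
    cover$percent_cover[cover$habitat_element %in% nonfocal],
    cover$territory[cover$habitat_element %in% nonfocal], sum, default = 0
  )
  # every (territory, element) with positive cover must have biomass means
  have <- unique(means[c("territory", "habitat_element")])
  need <- focal_cover[focal_cover$percent_cover > 0, , drop = FALSE]
  miss <- !paste(need$territory, need$habitat_element) %in%
    paste(have$territory, have$habitat_element)
  if (any(miss)) {
    stop_wrenlink(
      sprintf("cover includes element(s) with no biomass estimate: %s",
              paste(unique(paste(need$territory[miss],
                                 need$habitat_element[miss])),
                    collapse = "; ")),
      "wrenlink_coverage_mismatch_error"
    )
  }
  m <- merge(means, focal_cover, by = c("territory", "habitat_element"))
  m$contrib <- m$percent_cover / 100 * m[[value_col]] * area_m2
  out <- stats::aggregate(contrib ~ territory + stratum + taxon, data = m,
                          FUN = sum)
  names(out)[names(out) == "contrib"] <- "biomass_mg"
  if (all(out$biomass_mg == 0)) {
    warning("all availabilities are zero (zero cover or zero biomass)")
  }
  ord <- do.call(base::order, out[c("territory", "stratum", "taxon")])
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, nonfocal_cover = nonfocal_cover, area_m2 = area_m2)
}

#' Territory availability table with composition scores
#'
#' Assembles the per-territory, per-stratum availability surface used by the
#' performance analyses: one column per order plus the prey total (sum over
#' designated prey orders), the Hymenoptera total (kept as an independent
#' axis, never a prey order), and the first two axes of a PCA on relative
#' prey biomass (computed per stratum).
#'
#' @param availability Long table from [upscale()].
#' @param prey_orders Character vector of designated prey orders
#'   (Hymenoptera is removed if present).
#' @return Object of class `territory_availability`: data.frame with columns
#'   `territory`, `stratum`, one per order, `prey_total`, `hymenoptera_total`,
#'   `pc1`, `pc2`; PCA loadings per stratum in the `pca` attribute.
#' @export
territory_availability <- function(availability, prey_orders) {
  assert_columns(availability, c("territory", "stratum", "taxon",
                                 "biomass_mg"), "availability table")
  prey_orders <- setdiff(prey_orders, "Hymenoptera")
  wide_list <- lapply(split(availability, availability$stratum), function(d) {
    w <- tapply(d$biomass_mg, list(d$territory, d$taxon), sum, default = 0)
    terr <- rownames(w)
    prey <- intersect(prey_orders, colnames(w))
    out <- data.frame(territory = terr, stratum = d$stratum[1],
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(w))
    out$prey_total <- rowSums(w[, prey, drop = FALSE])
    out$hymenoptera_total <- if ("Hymenoptera" %in% colnames(w))
      w[, "Hymenoptera"] else 0
    rel <- relative_biomass(w[, prey, drop = FALSE])
    pca <- tryCatch(pca_composition(rel, n_axes = 2),
                    wrenlink_error = function(e) NULL)
    if (!is.null(pca)) {
      out$pc1 <- pca$scores[, 1]
      out$pc2 <- if (ncol(pca$scores) >= 2) pca$scores[, 2] else NA_real_
    } else {
      out$pc1 <- out$pc2 <- NA_real_
    }
    attr(out, "pca") <- pca
    out
  })
  pcas <- lapply(wide_list, attr, "pca")
  out <- do.call(rbind, lapply(wide_list, function(d) {
    attr(d, "pca") <- NULL
    d
  }))
  rownames(out) <- NULL
  structure(out, class = c("territory_availability", "data.frame"),
            pca = pcas, prey_orders = prey_orders)
}
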