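# Length -> biomass allometry and aggregation of field records to analysis
# cells (territory x habitat element x stratum x taxon).

#' Default allometric coefficient registry
#'
#' Power-law parameters `mass_mg = a * length_mm^b` per arthropod order or
#' suborder. These are editable literature-style defaults in the range
#' reported for temperate arthropod groups; they are configuration, not
#' ground truth, and any analysis should substitute coefficients appropriate
#' to its fauna. Hemiptera are parameterized at suborder level; taxa on the
#' exclusion list ([allometry_exclusions()]) have no coefficients and their
#' records yield no biomass estimate.
#'
#' @return Data.frame with columns `taxon`, `a` (mg mm^-b), `b`.
#' @export
default_allometry <- function() {
  data.frame(
    taxon = c("Araneae", "Coleoptera", "Diptera", "Heteroptera",
              "Auchenorrhyncha", "Sternorrhyncha", "Hemiptera",
              "Hymenoptera", "Isopoda", "Lepidoptera", "Orthoptera",
              "Blattodea", "Thysanoptera", "Dermaptera", "Neuroptera"),
    a = c(0.050, 0.041, 0.020, 0.026, 0.021, 0.018, 0.022,
          0.021, 0.033, 0.0047, 0.030, 0.025, 0.015, 0.030, 0.011),
    b = c(2.74, 2.64, 2.44, 2.50, 2.50, 2.30, 2.50,
          2.62, 2.40, 2.90, 2.55, 2.60, 2.30, 2.50, 2.60),
    stringsAsFactors = FALSE
  )
}

#' Taxa excluded from biomass estimation
#'
#' Orders for which no length-biomass parameters are available; their records
#' return a no-estimate sentinel (`NA`) rather than an error.
#'
#' @return Character vector of taxon labels.
#' @export
allometry_exclusions <- function() {
  c("Raphidoptera", "Archaeognatha", "Pseudoscorpionida", "Ephemeroptera",
    "Siphonaptera")
}

#' Convert counted-and-measured records to biomass
#'
#' For each record, biomass is `count * a * body_length_mm^b` with `(a, b)`
#' looked up by `taxon` (falling back to the `order` column when the suborder
#' label has no entry). Taxa on the exclusion list return `NA` with the
#' reason; any other unknown taxon is an error.
#'
#' @param records Data.frame with at least `taxon`, `count`,
#'   `body_length_mm`; an `order` column is used as lookup fallback.
#' @param registry Coefficient table, see [default_allometry()].
#' @param exclusions Taxa allowed to have no estimate.
#' @return Data.frame `mass_mg` (per record; `NA` for exclusions) and
#'   `no_estimate_reason`.
#' @export
length_to_mass <- function(records, registry = default_allometry(),
                           exclusions = allometry_exclusions()) {
  assert_columns(records, c("taxon", "count", "body_length_mm"),
                 "arthropod records")
  if (any(records$body_length_mm <= 0)) {
    stop_wrenlink("body lengths must be > 0", "wrenlink_input_error")
  }
  if (any(records$count < 1)) {
    stop_wrenlink("counts must be >= 1", "wrenlink_input_error")
  }
  idx <- match(records$taxon, registry$taxon)
  if ("order" %in% names(records)) {
    fb <- match(records$order, registry$taxon)
    idx[is.na(idx)] <- fb[is.na(idx)]
  }
  unknown <- is.na(idx) & !(records$taxon %in% exclusions)
  if (any(unknown)) {
    stop_wrenlink(
      sprintf("no allometric coefficients for taxon/taxa: %s",
              paste(unique(records$taxon[unknown]), collapse = ", ")),
      "wrenlink_registry_error"
    )
  }
  a <- registry$a[idx]
  b <- registry$b[idx]
  mass <- records$count * a * records$body_length_mm^b
  data.frame(
    mass_mg = mass,
    no_estimate_reason = ifelse(is.na(idx), "no length-biomass parameters",
                                NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Aggregate record-level biomass to analysis cells
#'
#' Sums per-record biomass within each (territory, habitat element, stratum,
#' taxon, time block, block) cell, then reduces: the mean across spatial
#' blocks (cells missing from a block are excluded from the mean, not counted
#' as zero), then — when `time_total = TRUE` — the total across time blocks.
#' The reductions are applied exactly in that order.
#'
#' @param records Arthropod records (see [length_to_mass()]) with the
#'   sampling-context columns `territory`, `habitat_element`, `stratum`,
#'   `block`, `time_block`. If a `mass_mg` column is absent it is computed
#'   from `registry`.
#' @param registry Allometric registry used when `mass_mg` is missing.
#' @param taxon_col Which column defines the taxon grouping (`"taxon"` keeps
#'   suborder resolution, `"order"` aggregates to order).
#' @param block_mean Average across spatial blocks (default TRUE).
#' @param time_total Sum across time blocks after block-averaging
#'   (default TRUE).
#' @return Data.frame with columns `territory`, `habitat_element`, `stratum`,
#'   `taxon`, (`time_block` when `time_total = FALSE`), `biomass_mg`, and
#'   `n_blocks` (blocks contributing to the mean).
#' @export
aggregate_cells <- function(records, registry = default_allometry(),
                            taxon_col = c("taxon", "order"),
                            block_mean = TRUE, time_total = TRUE) {
  taxon_col <- match.arg(taxon_col)
  if (!nrow(records)) {
    stop_wrenlink("no arthropod records to aggregate", "wrenlink_input_error")
  }
  assert_columns(records, c("territory", "habitat_element", "stratum",
                            "block", "time_block", taxon_col),
                 "arthropod records")
  if (!"mass_mg" %in% names(records)) {
    records$mass_mg <- length_to_mass(records, registry)$mass_mg
  }
  records <- records[!is.na(records$mass_mg), , drop = FALSE]
  records$taxon_grp <- records[[taxon_col]]
  sep <- "\r"
  unsplit_keys <- function(keys, cols) {
    parts <- strsplit(keys, sep, fixed = TRUE)
    out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(out) <- cols
    for (cc in intersect(c("time_block", "block"), cols)) {
      suppressWarnings(v <- as.integer(out[[cc]]))
      if (!anyNA(v)) out[[cc]] <- v
    }
    out
  }
  # per-sample-cell sums (block x time kept distinct)
  cols6 <- c("territory", "habitat_element", "stratum", "taxon_grp",
             "time_block", "block")
  k6 <- do.call(paste, c(records[cols6], sep = sep))
  s6 <- rowsum(records$mass_mg, k6)
  agg <- unsplit_keys(rownames(s6), cols6)
  agg$mass_mg <- s6[, 1]
  if (!block_mean) {
    names(agg)[names(agg) == "taxon_grp"] <- "taxon"
    names(agg)[names(agg) == "mass_mg"] <- "biomass_mg"
    rownames(agg) <- NULL
    return(agg)
  }
  # mean across spatial blocks (cells absent from a block excluded, not zero)
  cols5 <- cols6[1:5]
  k5 <- do.call(paste, c(agg[cols5], sep = sep))
  s5 <- rowsum(agg$mass_mg, k5)
  n5 <- rowsum(rep(1L, nrow(agg)), k5)
  bm <- unsplit_keys(rownames(s5), cols5)
  bm$mass_mg <- s5[, 1] / n5[, 1]
  bm$n_blocks <- n5[, 1]
  if (time_total) {
    cols4 <- cols6[1:4]
    k4 <- do.call(paste, c(bm[cols4], sep = sep))
    s4 <- rowsum(bm$mass_mg, k4)
    tt <- unsplit_keys(rownames(s4), cols4)
    tt$mass_mg <- s4[, 1]
    tt$n_blocks <- tapply(bm$n_blocks, k4, min)[rownames(s4)]
    bm <- tt
  }
  names(bm)[names(bm) == "taxon_grp"] <- "taxon"
  names(bm)[names(bm) == "mass_mg"] <- "biomass_mg"
  ord <- do.call(base::order, bm[intersect(
    c("territory", "habitat_element", "stratum", "taxon", "time_block"),
    names(bm))])
  bm <- bm[ord, , drop = FALSE]
  rownames(bm) <- NULL
  bm
}
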