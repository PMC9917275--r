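# Diet metabarcoding: similarity-threshold taxonomy cascade with LCA tie
# resolution, and diet composition metrics (FO, RRA, richness).

# Published operating points for COI barcode identity: minimum percent
# similarity qualifying an assignment at each rank. Comparisons are inclusive.
TAXONOMY_THRESHOLDS <- c(species = 99.3, genus = 94.9, family = 91,
                         order = 85.9)
RANK_ORDER <- c("order", "family", "genus", "species")

#' Default regional taxonomy overrides
#'
#' Regional faunal knowledge can refine a coarse assignment to species where
#' only one species occurs locally. The default list carries one rule:
#' OTUs resolved to family Armadillidiidae are assigned to
#' *Armadillidium vulgare*, the only armadillidiid in the study region.
#'
#' @return A list of override rules, each a list with `match_rank`,
#'   `match_name`, `set_rank`, `set_name`.
#' @export
default_overrides <- function() {
  list(list(match_rank = "family", match_name = "Armadillidiidae",
            set_rank = "species", set_name = "Armadillidium vulgare"))
}

#' Assign taxonomy to one OTU via the similarity-threshold cascade
#'
#' The best-match percent similarity caps the attainable rank: >= 99.3
#' species, >= 94.9 genus, >= 91 family, >= 85.9 order; below that the OTU is
#' unresolved and flagged excluded. When several candidates tie at the best
#' similarity with conflicting taxonomy, the assignment is the deepest rank on
#' which all tied candidates agree (their lowest common ancestor), still
#' capped by the threshold rank. Override rules (regional refinements) apply
#' last.
#'
#' @param candidates A data.frame with columns `order`, `family`, `genus`,
#'   `species`, `percent_similarity` (one row per candidate match), or an
#'   empty/zero-row data.frame for an unmatched OTU.
#' @param otu_id Identifier carried into the result.
#' @param overrides List of override rules (see [default_overrides()]).
#' @return A one-row data.frame: `otu_id`, `resolved_rank` (one of species,
#'   genus, family, order, unresolved), `resolved_name`, `order` (order-level
#'   component of the resolved path, `NA` if unresolved), `provenance`
#'   (threshold, lca, or override), `excluded` (logical).
#' @export
assign_taxonomy <- function(candidates, otu_id = "OTU",
                            overrides = default_overrides()) {
  empty <- function(provenance) {
    data.frame(otu_id = otu_id, resolved_rank = "unresolved",
               resolved_name = "", order = NA_character_,
               provenance = provenance, excluded = TRUE,
               stringsAsFactors = FALSE)
  }
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(empty("excluded"))
  }
  assert_columns(candidates,
                 c("order", "family", "genus", "species",
                   "percent_similarity"), "candidate table")
  if (any(is.na(candidates$order) | candidates$order == "")) {
    stop_wrenlink("malformed taxonomy path: candidate missing order",
                  "wrenlink_input_error")
  }
  if (any(candidates$percent_similarity < 0 |
            candidates$percent_similarity > 100)) {
    stop_wrenlink("percent similarity must lie in [0, 100]",
                  "wrenlink_input_error")
  }
  s_best <- max(candidates$percent_similarity)
  cap <- if (s_best >= TAXONOMY_THRESHOLDS["species"]) "species"
  else if (s_best >= TAXONOMY_THRESHOLDS["genus"]) "genus"
  else if (s_best >= TAXONOMY_THRESHOLDS["family"]) "family"
  else if (s_best >= TAXONOMY_THRESHOLDS["order"]) "order"
  else NA_character_
  if (is.na(cap)) return(empty("excluded"))
  tied <- candidates[abs(candidates$percent_similarity - s_best) < 1e-9, ,
                     drop = FALSE]
  # deepest rank on which all tied candidates agree (non-missing, identical)
  lca_rank <- NA_character_
  for (r in RANK_ORDER) {
    v <- tied[[r]]
    if (any(is.na(v) | v == "") || length(unique(v)) != 1L) break
    lca_rank <- r
  }
  if (is.na(lca_rank)) return(empty("excluded"))   # conflict at order level
  depth <- match(c(lca_rank, cap), RANK_ORDER)
  rank <- RANK_ORDER[min(depth)]
  provenance <- if (nrow(tied) > 1L && depth[1] < depth[2]) "lca"
  else "threshold"
  # fall back to the deepest non-missing rank at or above the cap
  name <- NA_character_
  for (r in RANK_ORDER[seq_len(match(rank, RANK_ORDER))]) {
    v <- tied[[r]][1]
    if (!is.na(v) && v != "") {
      rank_eff <- r
      name <- v
    }
  }
  res <- data.frame(otu_id = otu_id, resolved_rank = rank_eff,
                    resolved_name = name, order = tied$order[1],
                    provenance = provenance, excluded = FALSE,
                    stringsAsFactors = FALSE)
  for (rule in overrides) {
    if (identical(res$resolved_rank, rule$match_rank) &&
          identical(res$resolved_name, rule$match_name)) {
      res$resolved_rank <- rule$set_rank
      res$resolved_name <- rule$set_name
      res$provenance <- "override"
    }
  }
  res
}

#' Assign taxonomy for a whole match table
#'
#' Applies [assign_taxonomy()] to each OTU of a long-format match table (one
#' row per candidate). OTUs present in `otu_ids` but absent from the table are
#' treated as unmatched (unresolved, excluded).
#'
#' @param match_table Data.frame with columns `otu_id`, `order`, `family`,
#'   `genus`, `species`, `percent_similarity`.
#' @param overrides Override rules, see [default_overrides()].
#' @param otu_ids Optional full set of OTU ids to report on.
#' @return A data.frame with one row per OTU (columns as [assign_taxonomy()]).
#' @export
assign_taxonomy_table <- function(match_table,
                                  overrides = default_overrides(),
                                  otu_ids = NULL) {
  assert_columns(match_table, c("otu_id"), "match table")
  ids <- otu_ids %||% unique(match_table$otu_id)
  rows <- lapply(ids, function(id) {
    assign_taxonomy(match_table[match_table$otu_id == id, , drop = FALSE],
                    otu_id = id, overrides = overrides)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diet composition profile from assignments and an OTU read table
#'
#' Excluded OTUs are removed; samples retaining at least one read of a
#' retained OTU are the "positive" samples. Per order the profile reports:
#' frequency of occurrence, `FO = 100 * (samples containing the order) /
#' (positive samples)`; relative read abundance, the mean over positive
#' samples of the order's share of retained reads; the number of OTUs; and
#' the minimum species richness (distinct species-level names).
#'
#' @param assignments Output of [assign_taxonomy_table()].
#' @param otu_table Data.frame, first column `sample_id`, remaining columns
#'   one per OTU with nonnegative read counts.
#' @return An object of class `diet_profile`: a data.frame (one row per order,
#'   columns `order`, `fo`, `rra`, `n_otus`, `n_species`, `n_samples`) sorted
#'   by decreasing FO with alphabetical tie-break, with attribute
#'   `n_samples_positive`.
#' @export
diet_profile <- function(assignments, otu_table) {
  assert_columns(otu_table, "sample_id", "otu table")
  keep <- assignments[!assignments$excluded, , drop = FALSE]
  otus <- intersect(names(otu_table)[-1], keep$otu_id)
  if (!length(otus)) {
    stop_wrenlink("no retained OTUs: cannot form a diet profile",
                  "wrenlink_empty_profile_error")
  }
  reads <- as.matrix(otu_table[otus])
  storage.mode(reads) <- "double"
  if (any(reads < 0)) {
    stop_wrenlink("read counts must be nonnegative", "wrenlink_input_error")
  }
  pos <- rowSums(reads) > 0
  n_pos <- sum(pos)
  if (n_pos == 0L) {
    stop_wrenlink("no samples with retained arthropod reads",
                  "wrenlink_empty_profile_error")
  }
  reads <- reads[pos, , drop = FALSE]
  ord <- keep$order[match(otus, keep$otu_id)]
  orders <- sort(unique(ord))
  # per-sample per-order read totals
  order_reads <- sapply(orders, function(o) {
    rowSums(reads[, ord == o, drop = FALSE])
  })
  order_reads <- matrix(order_reads, nrow = n_pos,
                        dimnames = list(NULL, orders))
  present <- order_reads > 0
  fo <- 100 * colSums(present) / n_pos
  rra_mat <- order_reads / rowSums(reads)
  rra <- colMeans(rra_mat)
  n_otus <- vapply(orders, function(o) sum(ord == o), integer(1))
  n_species <- vapply(orders, function(o) {
    k <- keep[keep$order == o & keep$resolved_rank == "species", , drop = FALSE]
    length(unique(k$resolved_name))
  }, integer(1))
  out <- data.frame(order = orders, fo = fo, rra = rra, n_otus = n_otus,
                    n_species = n_species, n_samples = colSums(present),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fo, out$order), ]
  rownames(out) <- NULL
  structure(out, class = c("diet_profile", "data.frame"),
            n_samples_positive = n_pos)
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("Diet profile: %d orders across %d positive samples\n",
              nrow(x), attr(x, "n_samples_positive")))
  df <- as.data.frame(x)
  df$fo <- round(df$fo, 1)
  df$rra <- round(df$rra, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Designate prey orders from a diet profile
#'
#' Orders identified in more than one positive fecal sample (i.e. >= 2) are
#' prey; single-occurrence orders are excluded and listed with the reason.
#'
#' @param profile A [diet_profile()].
#' @param min_samples Minimum number of positive samples (default 2).
#' @return Character vector of prey order labels, with attribute `excluded`:
#'   a data.frame of non-prey orders and reasons.
#' @export
designate_prey <- function(profile, min_samples = 2L) {
  inc <- profile$n_samples >= min_samples
  excluded <- data.frame(
    order = profile$order[!inc],
    reason = sprintf("detected in %d sample(s) (< %d)",
                     profile$n_samples[!inc], min_samples),
    stringsAsFactors = FALSE
  )
  structure(sort(profile$order[inc]), excluded = excluded)
}
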