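# Synthetic study generator: emulates the four field data streams (diet OTU
# tables, arthropod samples, vegetation cover, nesting outcomes) with known
# latent structure, so every downstream stage can be tested without field data.

#' Construct a synthetic-study configuration
#'
#' Defines the full design of a simulated field study: spatial layout (sites,
#' territories, blocks), sampling layout (habitat elements, strata, time
#' blocks), the arthropod community model (negative-binomial counts with a
#' numerically dominant invasive ant, lognormal body lengths), vegetation cover
#' (Dirichlet fractions), the diet-detection model, and the causal link from
#' Lepidoptera availability to first egg date.
#'
#' Defaults reproduce the nominal field design: 8 territories in 3 sites
#' (3/2/3), 2 spatial blocks per territory, 9 habitat elements (8 dominant
#' plants plus bare ground), canopy and ground strata, and 5 time blocks
#' (three in the first season, two in the second).
#'
#' @param n_sites Number of sites.
#' @param territories_per_site Integer vector, territories in each site.
#' @param blocks_per_territory Spatial sampling blocks per territory.
#' @param habitat_elements Character vector of habitat-element labels.
#' @param strata Character vector of sampling strata.
#' @param time_blocks Number of sampling time blocks.
#' @param orders Character vector of arthropod order labels.
#' @param intensity 3-d array `[order, element, stratum]` of expected counts
#'   per sample cell. Defaults to a community with Hymenoptera numerical
#'   dominance and Lepidoptera concentrated in a few shrub canopies.
#' @param dispersion Negative-binomial size parameter (> 0); `Inf` selects the
#'   Poisson special case.
#' @param length_logmean,length_logsd Named per-order lognormal body-length
#'   parameters on the mm scale.
#' @param ant_dominance Probability a Hymenoptera individual is the invasive
#'   ant.
#' @param cover_concentration Named positive Dirichlet concentration over the
#'   habitat elements plus a non-focal `"other"` category.
#' @param diet_detection_prob Named per-order probability that an order is
#'   detected in a fecal sample.
#' @param n_diet_samples Number of fecal samples with detectable arthropod DNA.
#' @param n_total_samples Number of fecal samples collected (including
#'   amplification failures); recorded for reporting only.
#' @param reads_per_sample Sequencing depth per diet sample.
#' @param effect_lepidoptera Slope (days per SD) of first egg date on the
#'   z-scored territory Lepidoptera relative availability; positive values
#'   advance laying where Lepidoptera are relatively abundant.
#' @param date_intercept,date_sd First-egg-date model: mean Julian day and
#'   residual SD (days).
#' @param fledge_link Numeric `c(intercept, slope)` of the log-linear Poisson
#'   model for fledglings given centred first egg date.
#' @param element_dropout Probability that a habitat element is absent from a
#'   spatial block (emulates incomplete blocks); default 0 (off).
#' @param seed Integer seed for the bundle's private random stream.
#' @return An object of class `study_config` (a validated named list).
#' @seealso [generate_study()], [nominal_config()]
#' @export
study_config <- function(n_sites = 3L,
                         territories_per_site = c(3L, 2L, 3L),
                         blocks_per_territory = 2L,
                         habitat_elements = c("BARE", "NAGR", "EXGR", "OPLI",
                                              "BRSP", "ARCA", "ERFA", "RHIN",
                                              "SANI"),
                         strata = c("canopy", "ground"),
                         time_blocks = 5L,
                         orders = c("Araneae", "Coleoptera", "Diptera",
                                    "Hemiptera", "Hymenoptera", "Isopoda",
                                    "Lepidoptera", "Orthoptera"),
                         intensity = NULL,
                         dispersion = 0.7,
                         length_logmean = NULL,
                         length_logsd = NULL,
                         ant_dominance = 0.95,
                         cover_concentration = NULL,
                         diet_detection_prob = NULL,
                         n_diet_samples = 28L,
                         n_total_samples = 62L,
                         reads_per_sample = 2000L,
                         effect_lepidoptera = 10,
                         date_intercept = 100,
                         date_sd = 15,
                         fledge_link = c(intercept = 1.03, slope = -0.02),
                         element_dropout = 0,
                         seed = 1L) {
  if (is.null(intensity)) {
    intensity <- default_intensity(orders, habitat_elements, strata)
  }
  if (is.null(length_logmean)) {
    length_logmean <- default_length_logmean(orders)
  }
  if (is.null(length_logsd)) {
    length_logsd <- stats::setNames(rep(0.35, length(orders)), orders)
  }
  if (is.null(cover_concentration)) {
    cover_concentration <- default_cover_concentration(habitat_elements)
  }
  if (is.null(diet_detection_prob)) {
    diet_detection_prob <- default_detection_prob(orders)
  }
  cfg <- structure(list(
    n_sites = as.integer(n_sites),
    territories_per_site = as.integer(territories_per_site),
    blocks_per_territory = as.integer(blocks_per_territory),
    habitat_elements = habitat_elements,
    strata = strata,
    time_blocks = as.integer(time_blocks),
    orders = orders,
    intensity = intensity,
    dispersion = dispersion,
    length_logmean = length_logmean,
    length_logsd = length_logsd,
    ant_dominance = ant_dominance,
    cover_concentration = cover_concentration,
    diet_detection_prob = diet_detection_prob,
    n_diet_samples = as.integer(n_diet_samples),
    n_total_samples = as.integer(n_total_samples),
    reads_per_sample = as.integer(reads_per_sample),
    effect_lepidoptera = effect_lepidoptera,
    date_intercept = date_intercept,
    date_sd = date_sd,
    fledge_link = fledge_link,
    element_dropout = element_dropout,
    seed = as.integer(seed)
  ), class = "study_config")
  validate_study_config(cfg)
}

#' Nominal study configuration
#'
#' Returns the configuration matching the nominal field design counts:
#' 3 sites, 8 territories (3/2/3), 2 blocks per territory, 9 habitat elements,
#' canopy + ground strata, 5 time blocks.
#'
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
nominal_config <- function(...) study_config(...)

# Expected counts per sample cell: Hymenoptera numerically dominant in both
# strata, Hemiptera abundant in canopies, Isopoda a ground taxon, Lepidoptera
# concentrated on a subset of shrub canopies, Orthoptera tied to grasses.
default_intensity <- function(orders, elements, strata) {
  canopy <- c(Araneae = 3, Coleoptera = 3, Diptera = 2, Hemiptera = 8,
              Hymenoptera = 25, Isopoda = 0.5, Lepidoptera = 1.5,
              Orthoptera = 1)
  ground <- c(Araneae = 2, Coleoptera = 4, Diptera = 1, Hemiptera = 2,
              Hymenoptera = 25, Isopoda = 8, Lepidoptera = 0.5,
              Orthoptera = 2)
  arr <- array(0.5, dim = c(length(orders), length(elements), length(strata)),
               dimnames = list(orders, elements, strata))
  for (o in orders) {
    arr[o, , intersect("canopy", strata)] <- canopy[o] %||% 1
    arr[o, , intersect("ground", strata)] <- ground[o] %||% 1
  }
  arr[is.na(arr)] <- 1
  boost <- function(order, els, stratum, f) {
    els <- intersect(els, elements)
    if (order %in% orders && length(els) && stratum %in% strata) {
      arr[order, els, stratum] <<- arr[order, els, stratum] * f
    }
  }
  boost("Lepidoptera", c("ERFA", "SANI", "BRSP"), "canopy", 4)
  boost("Orthoptera", c("NAGR", "EXGR"), "canopy", 3)
  boost("Orthoptera", c("NAGR", "EXGR"), "ground", 3)
  boost("Isopoda", c("RHIN", "SANI"), "ground", 2)
  if ("BARE" %in% elements && "canopy" %in% strata) {
    arr[, "BARE", "canopy"] <- arr[, "BARE", "canopy"] * 0.5
  }
  arr
}

default_length_logmean <- function(orders) {
  base <- c(Araneae = log(3.5), Coleoptera = log(4), Diptera = log(3),
            Hemiptera = log(2.5), Hymenoptera = log(2.2), Isopoda = log(6),
            Lepidoptera = log(8), Orthoptera = log(8))
  out <- base[orders]
  out[is.na(out)] <- log(4)
  stats::setNames(out, orders)
}

# Concentration loosely proportional to typical territory cover shares:
# non-native grasses most common, then the dominant shrubs, with a non-focal
# remainder ("other": rare plants + artificial surfaces).
default_cover_concentration <- function(elements) {
  base <- c(BARE = 7, NAGR = 4, EXGR = 24, OPLI = 8, BRSP = 12, ARCA = 14,
            ERFA = 12, RHIN = 5, SANI = 3)
  conc <- base[elements]
  conc[is.na(conc)] <- 5
  names(conc) <- elements
  c(conc, other = 11)
}

# Per-order detection probabilities shaped like an insectivore diet: Diptera
# and Lepidoptera nearly ubiquitous, mid-frequency Orthoptera/Araneae/
# Coleoptera/Isopoda, Hymenoptera nearly absent despite environmental
# dominance (the diet/availability discordance the pipeline is built to show).
default_detection_prob <- function(orders) {
  base <- c(Araneae = 0.39, Coleoptera = 0.32, Diptera = 0.89,
            Hemiptera = 0.0, Hymenoptera = 0.036, Isopoda = 0.29,
            Lepidoptera = 0.82, Orthoptera = 0.43)
  p <- base[orders]
  p[is.na(p)] <- 0.2
  stats::setNames(p, orders)
}

validate_study_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!ok) stop_wrenlink(msg, "wrenlink_config_error")
  }
  chk(cfg$n_sites >= 1L, "n_sites must be >= 1")
  chk(length(cfg$territories_per_site) == cfg$n_sites,
      "territories_per_site must have one entry per site")
  chk(all(cfg$territories_per_site >= 1L), "territories_per_site must be >= 1")
  chk(cfg$blocks_per_territory >= 1L, "blocks_per_territory must be >= 1")
  chk(cfg$time_blocks >= 1L, "time_blocks must be >= 1")
  chk(cfg$dispersion > 0, "dispersion must be > 0")
  chk(cfg$ant_dominance >= 0 && cfg$ant_dominance <= 1,
      "ant_dominance must be in [0, 1]")
  chk(all(cfg$diet_detection_prob >= 0 & cfg$diet_detection_prob <= 1),
      "diet detection probabilities must be in [0, 1]")
  chk(all(cfg$intensity >= 0), "intensity entries must be >= 0")
  chk(all(cfg$cover_concentration > 0),
      "cover_concentration entries must be > 0")
  chk(cfg$element_dropout >= 0 && cfg$element_dropout < 1,
      "element_dropout must be in [0, 1)")
  dn <- dimnames(cfg$intensity)
  chk(identical(dim(cfg$intensity),
                c(length(cfg$orders), length(cfg$habitat_elements),
                  length(cfg$strata))) &&
        identical(dn[[1]], cfg$orders) &&
        identical(dn[[2]], cfg$habitat_elements) &&
        identical(dn[[3]], cfg$strata),
      "intensity dimensions must match orders x habitat_elements x strata")
  chk(identical(names(cfg$length_logmean), cfg$orders) &&
        identical(names(cfg$length_logsd), cfg$orders),
      "length parameters must be named by order")
  chk(identical(names(cfg$diet_detection_prob), cfg$orders),
      "diet_detection_prob must be named by order")
  cfg
}

territory_labels <- function(cfg) {
  sites <- sprintf("S%d", seq_len(cfg$n_sites))
  terr <- unlist(lapply(seq_len(cfg$n_sites), function(i) {
    sprintf("%s:T%d", sites[i], seq_len(cfg$territories_per_site[i]))
  }))
  data.frame(site = rep(sites, cfg$territories_per_site),
             territory = terr, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study bundle
#'
#' Draws all four data streams from the configured model: vegetation cover
#' (Dirichlet fractions per territory, summing to 100%), arthropod field
#' records (negative-binomial counts per sample cell, lognormal body lengths,
#' Hymenoptera split into invasive-ant and other individuals), nesting
#' outcomes (first egg date responding to the territory's latent Lepidoptera
#' relative availability, fledglings from a log-linear count model), and a
#' diet stream (per-order Bernoulli detection, then multinomial reads over the
#' detected orders' OTUs, plus a reference-match table with similarity
#' scores).
#'
#' The latent "Lepidoptera relative availability" driving first egg dates is
#' the Lepidoptera share of total prey biomass after cover-weighted upscaling
#' of the generated arthropod records (strata summed), i.e. the same quantity
#' the analysis pipeline later estimates. It is stored, z-scored, in the
#' bundle's `truth` record together with the realized date model.
#'
#' Generation uses a private random stream seeded from `config$seed`; the same
#' configuration always yields a bit-identical bundle and the caller's random
#' state is untouched.
#'
#' @param config A [study_config()].
#' @return An object of class `study_bundle`: a list with elements
#'   `otu_table` (samples x OTUs read counts), `match_table`, `arthropod_table`,
#'   `cover_table`, `nesting_table`, and `truth`.
#' @export
generate_study <- function(config) {
  config <- validate_study_config(config)
  with_seed(config$seed, {
    terr <- territory_labels(config)
    cover_table <- gen_cover(config, terr)
    arthropod_table <- gen_arthropods(config, terr)
    truth <- gen_truth(config, terr, arthropod_table, cover_table)
    nesting_table <- gen_nesting(config, terr, truth)
    diet <- gen_diet(config, terr)
    truth$sample_territory <- diet$sample_territory
    truth$n_total_samples <- config$n_total_samples
    structure(list(
      otu_table = diet$otu_table,
      match_table = diet$match_table,
      arthropod_table = arthropod_table,
      cover_table = cover_table,
      nesting_table = nesting_table,
      truth = truth
    ), class = "study_bundle")
  })
}

gen_cover <- function(cfg, terr) {
  conc <- cfg$cover_concentration
  cats <- names(conc)
  rows <- lapply(terr$territory, function(tt) {
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    pct <- 100 * g / sum(g)
    data.frame(territory = tt, habitat_element = cats, percent_cover = pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gen_arthropods <- function(cfg, terr) {
  grid <- expand.grid(
    order = cfg$orders,
    habitat_element = cfg$habitat_elements,
    stratum = cfg$strata,
    block = seq_len(cfg$blocks_per_territory),
    time_block = seq_len(cfg$time_blocks),
    territory = terr$territory,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$site <- terr$site[match(grid$territory, terr$territory)]
  mu <- cfg$intensity[cbind(grid$order, grid$habitat_element, grid$stratum)]
  if (is.finite(cfg$dispersion)) {
    counts <- stats::rnbinom(nrow(grid), mu = mu, size = cfg$dispersion)
  } else {
    counts <- stats::rpois(nrow(grid), lambda = mu)
  }
  if (cfg$element_dropout > 0) {
    cells <- unique(grid[c("territory", "block", "habitat_element")])
    drop <- stats::runif(nrow(cells)) < cfg$element_dropout
    dropped <- cells[drop, , drop = FALSE]
    if (nrow(dropped)) {
      key <- paste(grid$territory, grid$block, grid$habitat_element)
      counts[key %in% paste(dropped$territory, dropped$block,
                            dropped$habitat_element)] <- NA_integer_
    }
  }
  keep <- !is.na(counts) & counts > 0
  rec <- grid[keep, , drop = FALSE]
  rec$count <- counts[keep]
  rec$body_length_mm <- stats::rlnorm(
    nrow(rec),
    meanlog = cfg$length_logmean[rec$order],
    sdlog = cfg$length_logsd[rec$order]
  )
  # Hemiptera records carry suborder-level taxon labels.
  rec$taxon <- rec$order
  hemi <- which(rec$order == "Hemiptera")
  if (length(hemi)) {
    rec$taxon[hemi] <- sample(
      c("Heteroptera", "Auchenorrhyncha", "Sternorrhyncha"),
      length(hemi), replace = TRUE, prob = c(0.35, 0.4, 0.25)
    )
  }
  # Hymenoptera counts split into invasive-ant vs other individuals.
  rec$invasive_ant <- FALSE
  hym <- which(rec$order == "Hymenoptera")
  if (length(hym) && cfg$ant_dominance > 0) {
    n_ant <- stats::rbinom(length(hym), rec$count[hym], cfg$ant_dominance)
    other <- rec[hym, , drop = FALSE]
    other$count <- other$count - n_ant
    rec$count[hym] <- n_ant
    rec$invasive_ant[hym] <- TRUE
    other <- other[other$count > 0, , drop = FALSE]
    rec <- rbind(rec[rec$count > 0, , drop = FALSE], other)
  }
  rec$source <- ifelse(rec$stratum == "ground", "pitfall", "vacuum")
  vis <- which(rec$stratum == "canopy")
  if (length(vis)) {
    rec$source[vis][stats::runif(length(vis)) < 0.15] <- "visual"
  }
  cols <- c("site", "territory", "block", "time_block", "habitat_element",
            "stratum", "order", "taxon", "invasive_ant", "source", "count",
            "body_length_mm")
  rec <- rec[do.call(base::order, rec[c("territory", "block", "time_block",
                                        "habitat_element", "stratum",
                                        "taxon")]), cols]
  rownames(rec) <- NULL
  rec
}

# Latent territory-level Lepidoptera relative availability: run the same
# biomass -> block-mean -> time-total -> cover-weighting chain the analysis
# applies, then take the Lepidoptera share of prey (non-Hymenoptera) biomass.
gen_truth <- function(cfg, terr, arth, cover) {
  mass <- length_to_mass(arth, default_allometry())
  arth$mass_mg <- mass$mass_mg
  cell <- aggregate_cells(arth, taxon_col = "order")
  avail <- merge(cell, cover, by = c("territory", "habitat_element"))
  avail$w <- avail$percent_cover / 100 * avail$biomass_mg
  tot <- tapply(avail$w, list(avail$territory, avail$taxon), sum,
                default = 0)
  tot <- tot[terr$territory, , drop = FALSE]
  prey_cols <- setdiff(colnames(tot), "Hymenoptera")
  lep <- if ("Lepidoptera" %in% colnames(tot)) tot[, "Lepidoptera"] else
    rep(0, nrow(tot))
  share <- lep / pmax(rowSums(tot[, prey_cols, drop = FALSE]), 1e-12)
  z <- if (stats::sd(share) > 0) as.numeric(scale(share)) else share * 0
  list(
    lepidoptera_relative_availability = stats::setNames(share,
                                                        terr$territory),
    z_lepidoptera = stats::setNames(z, terr$territory),
    date_slope = -cfg$effect_lepidoptera,
    date_intercept = cfg$date_intercept
  )
}

gen_nesting <- function(cfg, terr, truth) {
  n <- nrow(terr)
  z <- truth$z_lepidoptera[terr$territory]
  date <- cfg$date_intercept - cfg$effect_lepidoptera * z +
    stats::rnorm(n, 0, cfg$date_sd)
  date <- pmin(pmax(round(date), 1L), 366L)
  attempts <- 1L + stats::rpois(n, 0.9)
  eggs <- vapply(attempts, function(a) {
    sum(pmax(1L, stats::rpois(a, 3.3)))
  }, integer(1))
  succ <- stats::rbinom(n, attempts, 0.55)
  lambda <- exp(cfg$fledge_link[[1]] +
                  cfg$fledge_link[[2]] * (date - cfg$date_intercept))
  fledge <- pmin(stats::rpois(n, lambda), eggs)
  data.frame(
    site = terr$site, territory = terr$territory,
    first_egg_julian = as.integer(date),
    nest_attempts = attempts,
    successful_clutches = pmin(succ, attempts),
    total_eggs = eggs,
    fledglings = as.integer(fledge),
    mortality_note = "none", stringsAsFactors = FALSE
  )
}

gen_diet <- function(cfg, terr) {
  orders <- cfg$orders
  p <- cfg$diet_detection_prob
  n_otus <- pmax(1L, round(8 * pmax(p, 0.05)))
  otu_order <- rep(orders, n_otus)
  otu_ids <- sprintf("OTU%03d", seq_along(otu_order))
  samples <- sprintf("FS%02d", seq_len(cfg$n_diet_samples))
  reads <- matrix(0L, nrow = length(samples), ncol = length(otu_ids),
                  dimnames = list(samples, otu_ids))
  for (i in seq_along(samples)) {
    det <- orders[stats::runif(length(orders)) < p]
    if (!length(det)) det <- sample(orders, 1, prob = pmax(p, 1e-6))
    pool <- which(otu_order %in% det)
    # within each detected order, 1..all of its OTUs occur
    present <- unlist(lapply(det, function(o) {
      ids <- which(otu_order == o)
      sample(ids, sample.int(length(ids), 1))
    }))
    w <- stats::rgamma(length(present), shape = 0.8)
    reads[i, present] <- stats::rmultinom(1, cfg$reads_per_sample,
                                          w / sum(w))[, 1]
  }
  otu_table <- as.data.frame(reads)
  otu_table <- cbind(data.frame(sample_id = samples, stringsAsFactors = FALSE),
                     otu_table)
  rownames(otu_table) <- NULL
  match_table <- gen_matches(otu_ids, otu_order)
  sample_territory <- stats::setNames(
    sample(terr$territory, length(samples), replace = TRUE), samples)
  list(otu_table = otu_table, match_table = match_table,
       sample_territory = sample_territory)
}

# Reference-database best matches: similarities drawn across the threshold
# bands so assignments span species..unresolved; every sixth OTU gets a second
# equal-similarity candidate (same genus, different species) to exercise the
# lowest-common-ancestor tie rule.
gen_matches <- function(otu_ids, otu_order) {
  n <- length(otu_ids)
  band <- sample(c("species", "genus", "family", "order", "none"), n,
                 replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.08, 0.07))
  lo <- c(species = 99.3, genus = 94.9, family = 91, order = 85.9, none = 75)
  hi <- c(species = 100, genus = 99.29, family = 94.89, order = 90.99,
          none = 85.8)
  sim <- round(stats::runif(n, lo[band], hi[band]), 2)
  fam <- sprintf("%s_fam%d", substr(otu_order, 1, 4),
                 1 + (seq_len(n) %% 3))
  gen <- sprintf("%s_gen%d", substr(otu_order, 1, 4),
                 1 + (seq_len(n) %% 5))
  spp <- sprintf("%s sp%d", gen, 1 + (seq_len(n) %% 7))
  base <- data.frame(otu_id = otu_ids, order = otu_order, family = fam,
                     genus = gen, species = spp, percent_similarity = sim,
                     stringsAsFactors = FALSE)
  tie <- base[seq_len(n) %% 6 == 0, , drop = FALSE]
  if (nrow(tie)) {
    tie$species <- sprintf("%s_alt", tie$species)
    base <- rbind(base, tie)
  }
  base <- base[order(base$otu_id, -base$percent_similarity), ]
  rownames(base) <- NULL
  base
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  cat(sprintf("  arthropod records : %d\n", nrow(x$arthropod_table)))
  cat(sprintf("  territories       : %d\n",
              length(unique(x$cover_table$territory))))
  cat(sprintf("  diet samples      : %d (OTUs: %d)\n",
              nrow(x$otu_table), ncol(x$otu_table) - 1L))
  cat(sprintf("  nesting records   : %d\n", nrow(x$nesting_table)))
  invisible(x)
}

#' Write or read a study configuration as JSON
#'
#' The configuration round-trips exactly: `read_config(write_config(cfg, f))`
#' reproduces `cfg` (numeric arrays restored with their dimnames).
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `study_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  for (nm in c("length_logmean", "length_logsd", "cover_concentration",
               "diet_detection_prob", "fledge_link")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  x$intensity <- list(
    values = as.vector(config$intensity),
    dim = dim(config$intensity),
    dimnames = dimnames(config$intensity)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  intensity <- array(x$intensity$values, dim = x$intensity$dim,
                     dimnames = x$intensity$dimnames)
  study_config(
    n_sites = x$n_sites,
    territories_per_site = x$territories_per_site,
    blocks_per_territory = x$blocks_per_territory,
    habitat_elements = x$habitat_elements,
    strata = x$strata,
    time_blocks = x$time_blocks,
    orders = x$orders,
    intensity = intensity,
    dispersion = if (is.character(x$dispersion)) Inf else x$dispersion,
    length_logmean = stats::setNames(unlist(x$length_logmean), x$orders),
    length_logsd = stats::setNames(unlist(x$length_logsd), x$orders),
    ant_dominance = x$ant_dominance,
    cover_concentration = unlist(x$cover_concentration),
    diet_detection_prob = stats::setNames(unlist(x$diet_detection_prob),
                                          x$orders),
    n_diet_samples = x$n_diet_samples,
    n_total_samples = x$n_total_samples,
    reads_per_sample = x$reads_per_sample,
    effect_lepidoptera = x$effect_lepidoptera,
    date_intercept = x$date_intercept,
    date_sd = x$date_sd,
    fledge_link = unlist(x$fledge_link),
    element_dropout = x$element_dropout,
    seed = x$seed
  )
}
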