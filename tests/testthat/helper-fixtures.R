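# Shared fixtures, all built in code.

# One-candidate match table row set for the taxonomy cascade.
cand <- function(similarity, order = "Isopoda", family = "Armadillidiidae",
                 genus = "Armadillidium", species = "Armadillidium vulgare") {
  data.frame(order = order, family = family, genus = genus, species = species,
             percent_similarity = similarity, stringsAsFactors = FALSE)
}

# Random candidate sets spanning all threshold bands, with occasional ties.
random_candidates <- function(n_cand, rng_similarity = c(80, 100)) {
  k <- sample.int(n_cand, 1)
  fam <- sprintf("fam%d", sample.int(3, k, replace = TRUE))
  gen <- sprintf("gen%d", sample.int(4, k, replace = TRUE))
  data.frame(
    order = sprintf("order%d", sample.int(2, k, replace = TRUE)),
    family = fam, genus = gen,
    species = sprintf("sp%d", sample.int(6, k, replace = TRUE)),
    percent_similarity = round(stats::runif(k, rng_similarity[1],
                                            rng_similarity[2]), 1),
    stringsAsFactors = FALSE
  )
}

rank_depth <- function(rank) {
  match(rank, c("unresolved", "order", "family", "genus", "species"))
}

# Small balanced arthropod record set: 2 territories x 2 elements x 2 strata
# x 2 blocks x 2 time blocks x 2 taxa, fixed lengths.
balanced_records <- function(noise_sd = 0, seed = 42) {
  grid <- expand.grid(
    territory = c("S1:T1", "S1:T2"), habitat_element = c("E1", "E2"),
    stratum = c("canopy", "ground"), block = 1:2, time_block = 1:2,
    taxon = c("Araneae", "Lepidoptera"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$site <- "S1"
  grid$count <- 2L
  set.seed(seed)
  grid$body_length_mm <- 5 + if (noise_sd > 0)
    abs(stats::rnorm(nrow(grid), 0, noise_sd)) else 0
  grid
}

# A tiny study configuration for fast property loops (not the nominal study
# conditions; used only where the property under test does not fix them).
tiny_config <- function(seed = 1, ...) {
  orders <- c("Araneae", "Lepidoptera")
  study_config(
    n_sites = 1L, territories_per_site = 2L, blocks_per_territory = 1L,
    habitat_elements = c("E1", "E2"), time_blocks = 1L, orders = orders,
    intensity = array(3, dim = c(2, 2, 2),
                      dimnames = list(orders, c("E1", "E2"),
                                      c("canopy", "ground"))),
    length_logmean = stats::setNames(c(log(4), log(6)), orders),
    length_logsd = stats::setNames(c(0.3, 0.3), orders),
    diet_detection_prob = stats::setNames(c(0.5, 0.8), orders),
    cover_concentration = c(E1 = 10, E2 = 10, other = 2),
    seed = seed, ...
  )
}
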