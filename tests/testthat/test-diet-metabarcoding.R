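test_that("similarity cascade resolves the worked threshold cases", {
  # clean species-level match
  a <- assign_taxonomy(cand(99.5, order = "Diptera", family = "Tipulidae",
                            genus = "Tipula", species = "Tipula sp1"))
  expect_equal(a$resolved_rank, "species")
  expect_equal(a$resolved_name, "Tipula sp1")
  expect_false(a$excluded)
  # equal-similarity tie, same genus different species -> genus via LCA
  tie <- rbind(cand(99.4, "Diptera", "Tipulidae", "Tipula", "Tipula sp1"),
               cand(99.4, "Diptera", "Tipulidae", "Tipula", "Tipula sp2"))
  a <- assign_taxonomy(tie)
  expect_equal(a$resolved_rank, "genus")
  expect_equal(a$resolved_name, "Tipula")
  expect_equal(a$provenance, "lca")
  # regional override: family Armadillidiidae -> Armadillidium vulgare
  a <- assign_taxonomy(cand(96, genus = NA, species = NA))
  expect_equal(a$resolved_rank, "species")
  expect_equal(a$resolved_name, "Armadillidium vulgare")
  expect_equal(a$provenance, "override")
  # below the order threshold -> unresolved and excluded
  a <- assign_taxonomy(cand(84))
  expect_equal(a$resolved_rank, "unresolved")
  expect_true(a$excluded)
})

test_that("threshold comparisons are inclusive at the published cutoffs", {
  ranks <- vapply(c(99.3, 94.9, 91, 85.9, 85.89), function(s) {
    assign_taxonomy(cand(s, order = "Diptera", family = "F", genus = "G",
                         species = "S"))$resolved_rank
  }, character(1))
  expect_equal(ranks, c("species", "genus", "family", "order", "unresolved"))
})

test_that("tied candidates conflicting at order level are excluded", {
  tie <- rbind(cand(99.4, "Diptera", "F1", "G1", "S1"),
               cand(99.4, "Lepidoptera", "F2", "G2", "S2"))
  a <- assign_taxonomy(tie)
  expect_equal(a$resolved_rank, "unresolved")
  expect_true(a$excluded)
})

test_that("cascade rejects malformed candidates and empty matches resolve", {
  expect_error(assign_taxonomy(cand(99, order = NA)),
               class = "wrenlink_input_error")
  expect_error(assign_taxonomy(cand(101)), class = "wrenlink_input_error")
  a <- assign_taxonomy(data.frame())
  expect_true(a$excluded)
})

test_that("raising the best similarity never lowers the rank (property)", {
  set.seed(101)
  for (i in 1:300) {
    cands <- random_candidates(3)
    a0 <- assign_taxonomy(cands, overrides = list())
    best <- cands$percent_similarity == max(cands$percent_similarity)
    cands$percent_similarity[best] <- pmin(
      100, cands$percent_similarity[best] + stats::runif(1, 0, 10))
    a1 <- assign_taxonomy(cands, overrides = list())
    expect_gte(rank_depth(a1$resolved_rank), rank_depth(a0$resolved_rank))
  }
})

test_that("LCA assignments are ancestors of every tied candidate (property)", {
  set.seed(202)
  for (i in 1:300) {
    cands <- random_candidates(4)
    # force an exact tie at the top
    s <- max(cands$percent_similarity)
    cands$percent_similarity[cands$percent_similarity > s - 3] <- s
    a <- assign_taxonomy(cands, overrides = list())
    if (a$excluded) next
    tied <- cands[cands$percent_similarity == s, , drop = FALSE]
    expect_true(all(tied[[a$resolved_rank]] == a$resolved_name))
  }
})

# A fixed OTU read table: 28 positive samples, Diptera OTUs in 25 of them.
fo_fixture <- function() {
  samples <- sprintf("FS%02d", 1:28)
  otu <- data.frame(sample_id = samples)
  otu$OTU1 <- c(rep(10L, 25), 0L, 0L, 0L)      # Diptera
  otu$OTU2 <- c(rep(0L, 25), 5L, 5L, 5L)       # Lepidoptera
  otu$OTU3 <- rep(2L, 28)                      # Lepidoptera
  asg <- data.frame(
    otu_id = c("OTU1", "OTU2", "OTU3"),
    resolved_rank = c("species", "genus", "species"),
    resolved_name = c("Tipula sp1", "Arachnis", "Arachnis picta"),
    order = c("Diptera", "Lepidoptera", "Lepidoptera"),
    provenance = "threshold", excluded = FALSE, stringsAsFactors = FALSE
  )
  list(otu = otu, asg = asg)
}

test_that("frequency of occurrence and RRA follow their definitions", {
  fx <- fo_fixture()
  prof <- diet_profile(fx$asg, fx$otu)
  expect_equal(attr(prof, "n_samples_positive"), 28L)
  expect_equal(round(prof$fo[prof$order == "Diptera"], 1), 89.3)
  expect_equal(prof$fo[prof$order == "Lepidoptera"], 100)
  # RRA: Diptera samples have 10/12 of reads, the last three have 0
  expect_equal(prof$rra[prof$order == "Diptera"], 25 * (10 / 12) / 28)
  # order present in 3 of 4 positive samples -> FO 75
  small <- fx$otu[1:4, ]
  small$OTU1 <- c(1L, 1L, 1L, 0L)
  p2 <- diet_profile(fx$asg, small)
  expect_equal(p2$fo[p2$order == "Diptera"], 75)
  # a single sample with all reads in one order -> RRA 1
  one <- data.frame(sample_id = "FS01", OTU1 = 7L)
  p3 <- diet_profile(fx$asg, one)
  expect_equal(p3$rra, 1)
  expect_equal(p3$n_otus, 1L)
})

test_that("FO and prey designation are invariant to read rescaling", {
  fx <- fo_fixture()
  prof <- diet_profile(fx$asg, fx$otu)
  scaled <- fx$otu
  scaled[-1] <- scaled[-1] * rep(c(3L, 7L), length.out = nrow(scaled))
  prof2 <- diet_profile(fx$asg, scaled)
  expect_equal(prof2$fo, prof$fo)
  expect_equal(prof2$rra, prof$rra)  # per-sample proportions are unchanged
  expect_identical(as.character(designate_prey(prof2)),
                   as.character(designate_prey(prof)))
})

test_that("prey designation needs more than one positive sample", {
  fx <- fo_fixture()
  fx$otu$OTU1 <- c(4L, rep(0L, 27))            # Diptera now in 1 sample
  prof <- diet_profile(fx$asg, fx$otu)
  prey <- designate_prey(prof)
  expect_identical(as.character(prey), "Lepidoptera")
  expect_equal(attr(prey, "excluded")$order, "Diptera")
  empty <- prof[0, , drop = FALSE]
  expect_length(designate_prey(empty), 0)
})

test_that("profiles fail cleanly without positive samples or retained OTUs", {
  fx <- fo_fixture()
  fx$asg$excluded <- TRUE
  expect_error(diet_profile(fx$asg, fx$otu),
               class = "wrenlink_empty_profile_error")
  fx2 <- fo_fixture()
  fx2$otu[-1] <- 0L
  expect_error(diet_profile(fx2$asg, fx2$otu),
               class = "wrenlink_empty_profile_error")
})

test_that("FO converges to the configured detection probability", {
  cfg <- nominal_config(seed = 31, n_diet_samples = 400L)
  b <- generate_study(cfg)
  # assignments from the generator's true order labels (no exclusions), so
  # the comparison isolates the FO metric against the detection model
  truth_order <- b$match_table[!duplicated(b$match_table$otu_id),
                               c("otu_id", "order")]
  asg <- data.frame(otu_id = truth_order$otu_id, resolved_rank = "order",
                    resolved_name = truth_order$order,
                    order = truth_order$order, provenance = "threshold",
                    excluded = FALSE, stringsAsFactors = FALSE)
  prof <- diet_profile(asg, b$otu_table)
  for (o in c("Diptera", "Lepidoptera", "Orthoptera", "Araneae")) {
    p <- cfg$diet_detection_prob[o]
    se <- sqrt(p * (1 - p) / 400) * 100
    expect_lt(abs(prof$fo[prof$order == o] - 100 * p), 3 * se)
  }
})
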