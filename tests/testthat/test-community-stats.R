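test_that("Bray-Curtis matches its closed form and the worked cases", {
  expect_equal(bray_curtis(c(2, 3, 0), c(2, 3, 0)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 4, 0)), 1)
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 4 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "wrenlink_undefined_distance_error")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)),
               class = "wrenlink_input_error")
})

test_that("Bray-Curtis is symmetric, bounded, zero iff equal (property)", {
  set.seed(11)
  for (i in 1:100) {
    x <- stats::rpois(6, 3)
    y <- stats::rpois(6, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis(x, y)
    expect_equal(bray_curtis(y, x), d)
    expect_gte(d, 0)
    expect_lte(d, 1)
    if (all(x == y)) expect_equal(d, 0) else expect_gt(d, 0)
  }
})

test_that("the distance matrix agrees with vegan's implementation", {
  set.seed(21)
  m <- matrix(stats::rpois(8 * 6, 4) + 1, nrow = 8)
  got <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F matches adonis2 and is seed-reproducible", {
  set.seed(31)
  m <- matrix(stats::rlnorm(12 * 4), nrow = 12)
  m[7:12, 1] <- m[7:12, 1] + 2
  g <- rep(c("a", "b"), each = 6)
  d <- bray_curtis_matrix(m)
  got <- permanova(d, g, n_permutations = 199, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 199)
  expect_equal(got$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(got$p_value,
               permanova(d, g, n_permutations = 199, seed = 5)$p_value)
  expect_gt(got$p_value, 0)
  expect_lte(got$p_value, 1)
})

test_that("PERMANOVA rejects degenerate designs", {
  d <- bray_curtis_matrix(matrix(stats::runif(12), nrow = 4))
  expect_error(permanova(d, rep("a", 4)), class = "wrenlink_design_error")
  expect_error(permanova(d, c("a", "a", "a", "b")),
               class = "wrenlink_design_error")
  expect_error(permanova(matrix(1, 4, 4), rep(c("a", "b"), 2)),
               class = "wrenlink_input_error")
})

test_that("pseudo-F survives point duplication up to the df scaling", {
  # brute-force oracle: explicit Anderson partitioning from the raw distances
  brute_f <- function(d, g) {
    n <- nrow(d)
    ss <- function(idx) {
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
      s / length(idx)
    }
    sst <- ss(seq_len(n))
    ssw <- sum(vapply(unique(g), function(l) ss(which(g == l)), numeric(1)))
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  set.seed(41)
  m <- matrix(stats::rlnorm(8 * 3), nrow = 8)
  g <- rep(c("a", "b"), each = 4)
  p1 <- permanova(bray_curtis_matrix(m), g, n_permutations = 9, seed = 1)
  expect_equal(p1$pseudo_f, brute_f(bray_curtis_matrix(m), g),
               tolerance = 1e-10)
  d2 <- bray_curtis_matrix(rbind(m, m))
  p2 <- permanova(d2, c(g, g), n_permutations = 9, seed = 1)
  expect_equal(p2$pseudo_f, brute_f(d2, c(g, g)), tolerance = 1e-10)
  # with doubled membership the separation persists and F grows with the df
  expect_gt(p2$pseudo_f, p1$pseudo_f)
})

test_that("composition PCA matches an eigendecomposition oracle", {
  set.seed(51)
  raw <- matrix(stats::rlnorm(8 * 6), nrow = 8)
  m <- relative_biomass(raw)
  p <- pca_composition(m)
  # reconstruction of the centered matrix from all axes
  centered <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(centered),
               tolerance = 1e-10, ignore_attr = TRUE)
  # eigenvalue oracle
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev[seq_along(p$sdev)], tolerance = 1e-10)
  expect_equal(sum(p$variance_fraction_all), 1)
  expect_true(all(diff(p$variance_fraction_all) < 1e-12))
  # scores are orthogonal
  gram <- crossprod(p$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # sign convention: the largest-magnitude loading on each axis is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("PCA handles two-column trade-offs and degenerate input", {
  x1 <- c(0.1, 0.4, 0.7, 0.9)
  m <- cbind(a = x1, b = 1 - x1)
  p <- pca_composition(m)
  expect_equal(p$variance_fraction[1], 1)
  expect_error(pca_composition(matrix(0.5, 4, 2)),
               class = "wrenlink_zero_variance_error")
  expect_error(pca_composition(m[1, , drop = FALSE]),
               class = "wrenlink_input_error")
})

test_that("marginal means equal the balanced-design cell-mean oracle", {
  # noiseless limit: the mean is log1p of the constant cell value
  rec <- balanced_records(noise_sd = 0)
  rec$mass_mg <- length_to_mass(rec)$mass_mg
  samples <- aggregate_cells(rec, block_mean = FALSE)
  mm <- marginal_means(samples)
  cellval <- c(tapply(samples$biomass_mg, samples$taxon, unique))
  expect_equal(mm$mean, unname(log1p(cellval[mm$taxon])), tolerance = 1e-12)
  expect_equal(attr(mm, "transform_scale"), "log1p")
  # noisy balanced data: brute-force cell means of the log1p response
  rec <- balanced_records(noise_sd = 2, seed = 9)
  rec$mass_mg <- length_to_mass(rec)$mass_mg
  samples <- aggregate_cells(rec, block_mean = FALSE)
  mm <- marginal_means(samples)
  key <- paste(samples$territory, samples$habitat_element, samples$stratum,
               samples$taxon)
  oracle <- c(tapply(log1p(samples$biomass_mg), key, mean))
  expect_equal(mm$mean,
               unname(oracle[paste(mm$territory, mm$habitat_element,
                                   mm$stratum, mm$taxon)]),
               tolerance = 1e-8)
  # raw scale is exposed for the upscaling path
  mm_raw <- marginal_means(samples, transform = "raw")
  oracle_raw <- c(tapply(samples$biomass_mg, key, mean))
  expect_equal(mm_raw$mean,
               unname(oracle_raw[paste(mm_raw$territory,
                                       mm_raw$habitat_element,
                                       mm_raw$stratum, mm_raw$taxon)]),
               tolerance = 1e-8)
})

test_that("a missing block shrinks the cell's n and inflates its SE", {
  rec <- balanced_records(noise_sd = 2, seed = 13)
  rec$mass_mg <- length_to_mass(rec)$mass_mg
  samples <- aggregate_cells(rec, block_mean = FALSE)
  drop <- samples$territory == "S1:T1" & samples$habitat_element == "E1" &
    samples$block == 2 & samples$time_block == 1
  reduced <- samples[!drop, , drop = FALSE]
  mm <- marginal_means(reduced)
  cell <- mm[mm$territory == "S1:T1" & mm$habitat_element == "E1", ]
  full <- marginal_means(samples)
  cellf <- full[full$territory == "S1:T1" & full$habitat_element == "E1", ]
  expect_true(all(cell$n <= cellf$n))
  expect_true(any(cell$n < cellf$n))
  # hand aggregation of the reduced fixture
  key <- paste(reduced$territory, reduced$habitat_element, reduced$stratum,
               reduced$taxon)
  oracle <- c(tapply(log1p(reduced$biomass_mg), key, mean))
  expect_equal(mm$mean, unname(oracle[paste(mm$territory, mm$habitat_element,
                                            mm$stratum, mm$taxon)]),
               tolerance = 1e-12)
})

test_that("the mixed-model refinement reproduces cell means when balanced", {
  rec <- balanced_records(noise_sd = 2, seed = 17)
  rec$mass_mg <- length_to_mass(rec)$mass_mg
  samples <- aggregate_cells(rec, block_mean = FALSE)
  cm <- marginal_means(samples, method = "cellmeans")
  lmm <- marginal_means(samples, method = "lmm")
  expect_equal(lmm$mean, cm$mean, tolerance = 1e-6)
})
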