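test_that("nesting summary reproduces the packaged-table statistics", {
  s <- summarize_nesting(example_nesting_table())
  get <- function(metric, col) s[[col]][s$metric == metric]
  expect_equal(round(get("nest_attempts", "mean"), 1), 1.9)
  expect_equal(round(get("nest_attempts", "se"), 2), 0.35)
  expect_equal(round(get("clutch_size", "mean"), 1), 3.3)
  expect_equal(round(get("clutch_size", "se"), 2), 0.25)
  expect_equal(round(get("total_eggs", "mean"), 1), 6.4)
  expect_equal(round(get("total_eggs", "se"), 2), 1.39)
  expect_equal(round(get("fledglings", "mean"), 1), 2.8)
  expect_equal(round(get("fledglings", "se"), 2), 0.92)
  # the per-territory-ratio reading is the default; pooled is also reported
  expect_equal(attr(s, "pooled_clutch"), 51 / 15)
})

test_that("identical records give zero SE and zero attempts are excluded", {
  two <- example_nesting_table()[c(1, 1), ]
  s <- summarize_nesting(two)
  expect_true(all(s$se == 0))
  rec <- example_nesting_table()
  rec$nest_attempts[1] <- 0L
  expect_warning(s2 <- summarize_nesting(rec), "zero nest attempts")
  expect_equal(s2$n[s2$metric == "clutch_size"], 7L)
  expect_error(summarize_nesting(rec[1, , drop = FALSE]),
               class = "wrenlink_input_error")
})

mk_avail <- function(x, territory = sprintf("T%d", seq_along(x))) {
  data.frame(territory = territory, stratum = "canopy", pred = x,
             stringsAsFactors = FALSE)
}

mk_resp <- function(y, territory = sprintf("T%d", seq_along(y))) {
  data.frame(territory = territory, resp = y, stringsAsFactors = FALSE)
}

test_that("gaussian links recover exact collinearity and reject degeneracy", {
  x <- c(1, 2, 3, 5, 8, 9, 11, 12)
  # the noiseless fit triggers lm's perfect-fit warning by construction
  lk <- suppressWarnings(relate(mk_avail(x), mk_resp(2 * x + 3), "pred",
                                "resp"))
  expect_equal(lk$correlation, 1)
  expect_equal(lk$r_squared, 1)
  expect_equal(lk$estimate, 2)
  expect_error(relate(mk_avail(rep(4, 8)), mk_resp(x), "pred", "resp"),
               class = "wrenlink_degenerate_fit_error")
  expect_error(relate(mk_avail(x[1:3]), mk_resp(x[1:3]), "pred", "resp"),
               class = "wrenlink_input_error")
})

test_that("gaussian links are invariant to affine predictor rescaling", {
  set.seed(71)
  x <- stats::runif(8, 0, 10)
  y <- 50 - 2 * x + stats::rnorm(8, 0, 3)
  a <- relate(mk_avail(x), mk_resp(y), "pred", "resp")
  b <- relate(mk_avail(100 * x - 7), mk_resp(y), "pred", "resp")
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$r_squared, a$r_squared)
})

test_that("poisson links model counts on the log scale", {
  set.seed(72)
  x <- seq(-1, 1, length.out = 8)
  y <- stats::rpois(8, exp(1 + 1.2 * x))
  lk <- relate(mk_avail(x), mk_resp(y), "pred", "resp", family = "poisson")
  ref <- stats::glm(y ~ x, family = stats::poisson())
  expect_equal(lk$estimate, unname(stats::coef(ref)[2]))
  expect_true(is.na(lk$r_squared))
})

test_that("null predictors reject at the nominal rate (calibration)", {
  set.seed(73)
  n_rej <- 0
  for (i in 1:400) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8)
    lk <- relate(mk_avail(x), mk_resp(y), "pred", "resp")
    if (lk$p_value <= 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej / 400, 0.02)
  expect_lt(n_rej / 400, 0.08)
})

disc_profile <- function(orders, fo) {
  structure(data.frame(order = orders, fo = fo, rra = fo / 100,
                       n_otus = 1L, n_species = 1L,
                       n_samples = pmax(2L, round(fo / 10)),
                       stringsAsFactors = FALSE),
            class = c("diet_profile", "data.frame"),
            n_samples_positive = 28L)
}

disc_avail <- function(orders, biomass) {
  d <- data.frame(territory = "T1", stratum = "ground",
                  stringsAsFactors = FALSE)
  for (i in seq_along(orders)) d[[orders[i]]] <- biomass[i]
  d <- rbind(d, d)
  d$territory <- c("T1", "T2")
  d$prey_total <- rowSums(d[orders])
  d$hymenoptera_total <- 0
  d$pc1 <- d$pc2 <- 0
  d
}

test_that("rank discordance recovers agreement, reversal and the flags", {
  orders <- c("Diptera", "Lepidoptera", "Hymenoptera", "Hemiptera")
  fo <- c(89.3, 82.1, 3.6, 0.1)
  same <- rank_discordance(disc_profile(orders, fo),
                           disc_avail(orders, c(40, 30, 20, 10)))
  expect_equal(same$spearman_rho, 1)
  rev <- rank_discordance(disc_profile(orders, fo),
                          disc_avail(orders, c(10, 20, 30, 40)))
  expect_equal(rev$spearman_rho, -1)
  flags <- rev$table$flag[match(c("Diptera", "Lepidoptera"),
                                rev$table$order)]
  expect_true(all(flags == "high_diet_low_availability"))
  expect_true(all(rev$table$flag[match(c("Hymenoptera", "Hemiptera"),
                                       rev$table$order)] ==
                    "low_diet_high_availability"))
})

test_that("rank discordance is invariant to monotone transforms (property)", {
  set.seed(74)
  orders <- sprintf("O%d", 1:6)
  fo <- sort(stats::runif(6, 1, 99), decreasing = TRUE)
  bm <- stats::runif(6, 1, 50)
  base <- rank_discordance(disc_profile(orders, fo),
                           disc_avail(orders, bm))
  warped <- rank_discordance(disc_profile(orders, 99 * (fo / 99)^3),
                             disc_avail(orders, exp(bm / 10)))
  expect_equal(warped$spearman_rho, base$spearman_rho)
  expect_equal(warped$table$availability_rank, base$table$availability_rank)
  # disjoint order sets are an error; partial overlap is reported
  expect_error(rank_discordance(disc_profile(c("A", "B"), c(50, 40)),
                                disc_avail(orders, bm)),
               class = "wrenlink_input_error")
  part <- rank_discordance(disc_profile(c(orders[1:3], "Zoraptera"),
                                        c(90, 60, 30, 10)),
                           disc_avail(orders, bm))
  expect_equal(part$orders_diet_only, "Zoraptera")
  expect_setequal(part$orders_availability_only, orders[4:6])
})
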