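# Nesting-outcome summaries and territory-level links between arthropod
# availability and reproductive performance.

#' Read the packaged eight-territory nesting-outcome table
#'
#' One season of cactus wren nest monitoring across eight territories in
#' three sites: first egg date (Julian day), nest attempts, successful
#' clutches, total eggs, fledglings and mortality notes.
#'
#' @return Data.frame of nesting records.
#' @export
example_nesting_table <- function() {
  path <- system.file("extdata", "nesting_2012.csv", package = "wrenlink",
                      mustWork = TRUE)
  read_nesting(path)
}

#' Summarize nesting outcomes across territories
#'
#' Means and standard errors (sample SD over sqrt(n)) across territories of
#' nest attempts, clutch size, seasonal total eggs, and fledglings. Clutch
#' size is computed per territory as `total_eggs / nest_attempts` and then
#' averaged across territories (the default reading); the pooled ratio
#' `sum(eggs) / sum(attempts)` is also reported. Territories with zero
#' attempts have undefined clutch size and are excluded from that metric with
#' a warning.
#'
#' @param records Data.frame of nesting records with columns
#'   `nest_attempts`, `total_eggs`, `fledglings` (see
#'   [example_nesting_table()]).
#' @return Object of class `nesting_summary`: data.frame with one row per
#'   metric (`metric`, `mean`, `se`, `n`) plus attribute `pooled_clutch`.
#' @export
summarize_nesting <- function(records) {
  assert_columns(records, c("nest_attempts", "total_eggs", "fledglings"),
                 "nesting records")
  if (nrow(records) < 2L) {
    stop_wrenlink("need >= 2 nesting records to summarize",
                  "wrenlink_input_error")
  }
  ok <- records$nest_attempts > 0
  if (any(!ok)) {
    warning(sprintf(
      "%d territory(ies) with zero nest attempts excluded from clutch size",
      sum(!ok)))
  }
  clutch <- records$total_eggs[ok] / records$nest_attempts[ok]
  metrics <- list(
    nest_attempts = records$nest_attempts,
    clutch_size = clutch,
    total_eggs = records$total_eggs,
    fledglings = records$fledglings
  )
  out <- data.frame(
    metric = names(metrics),
    mean = vapply(metrics, mean, numeric(1)),
    se = vapply(metrics, std_err, numeric(1)),
    n = vapply(metrics, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("nesting_summary", "data.frame"),
            pooled_clutch = sum(records$total_eggs[ok]) /
              sum(records$nest_attempts[ok]))
}

#' @export
print.nesting_summary <- function(x, ...) {
  cat("Nesting summary across territories\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, 1)
  df$se <- round(df$se, 2)
  print(df, row.names = FALSE)
  cat(sprintf("  pooled clutch (sum eggs / sum attempts): %.2f\n",
              attr(x, "pooled_clutch")))
  invisible(x)
}

#' Relate territory availability to a nesting response
#'
#' Territory-level regression with each territory as the unit of
#' replication. For `family = "gaussian"` the result is the Pearson
#' correlation test plus the simple linear fit (slope, R-squared, two-sided
#' p). For `family = "poisson"` (count responses such as fledglings) it is a
#' log-link GLM slope with its Wald p-value. The predictor can optionally be
#' log-transformed (used for heavy-tailed non-native arthropod biomass).
#'
#' @param availability A [territory_availability()] table (or any data.frame
#'   with `territory` plus the predictor column), optionally filtered to one
#'   stratum first.
#' @param records Nesting records with a `territory` column and the response.
#' @param predictor,response Column names.
#' @param family `"gaussian"` or `"poisson"`.
#' @param log_predictor Apply `log()` to the predictor before fitting.
#' @param stratum Optional stratum filter applied to `availability`.
#' @return Object of class `link_result`: list with `predictor`, `response`,
#'   `estimate` (slope), `statistic`, `p_value`, `r_squared` (gaussian only),
#'   `n`, `family`, and the underlying `fit`.
#' @export
relate <- function(availability, records, predictor, response,
                   family = c("gaussian", "poisson"),
                   log_predictor = FALSE, stratum = NULL) {
  family <- match.arg(family)
  av <- as.data.frame(availability)
  if (!is.null(stratum)) av <- av[av$stratum == stratum, , drop = FALSE]
  assert_columns(av, c("territory", predictor), "availability table")
  assert_columns(records, c("territory", response), "nesting records")
  d <- merge(av[c("territory", predictor)],
             records[c("territory", response)], by = "territory")
  if (nrow(d) < 4L) {
    stop_wrenlink("need >= 4 matched territories", "wrenlink_input_error")
  }
  x <- d[[predictor]]
  if (log_predictor) x <- log(x)
  y <- d[[response]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_wrenlink("constant predictor or response: degenerate fit",
                  "wrenlink_degenerate_fit_error")
  }
  if (family == "gaussian") {
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    res <- list(estimate = unname(stats::coef(fit)[2]),
                statistic = unname(ct$statistic),
                p_value = ct$p.value,
                r_squared = summary(fit)$r.squared,
                correlation = unname(ct$estimate))
  } else {
    fit <- stats::glm(y ~ x, family = stats::poisson())
    sm <- summary(fit)$coefficients
    res <- list(estimate = unname(sm["x", "Estimate"]),
                statistic = unname(sm["x", "z value"]),
                p_value = unname(sm["x", "Pr(>|z|)"]),
                r_squared = NA_real_,
                correlation = NA_real_)
  }
  structure(c(list(predictor = predictor, response = response,
                   family = family, n = nrow(d),
                   log_predictor = log_predictor,
                   caveat = "raw p-value; no multiple-testing correction"),
              res, list(fit = fit)),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("%s ~ %s (%s, n = %d)\n", x$response,
              if (x$log_predictor) paste0("log(", x$predictor, ")") else
                x$predictor, x$family, x$n))
  cat(sprintf("  slope = %.4g, p = %.4g", x$estimate, x$p_value))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.2f", x$r_squared))
  cat("\n  note:", x$caveat, "\n")
  invisible(x)
}

#' Diet-rank versus availability-rank discordance report
#'
#' Pairs each order's rank in the diet (by frequency of occurrence) with its
#' rank in environmental biomass for a stratum and computes Spearman's rank
#' correlation (midranks for ties). Orders present in only one input are
#' listed separately. Orders in the top half of diet ranks but bottom half of
#' availability ranks are flagged `high_diet_low_availability` (and vice
#' versa), surfacing the diet/availability discordance.
#'
#' @param profile A [diet_profile()].
#' @param availability A [territory_availability()] table.
#' @param stratum Stratum whose biomass ranks are used (default first).
#' @return Object of class `rank_discordance`: list with `table` (order,
#'   diet FO, mean biomass, both ranks, flag), `spearman_rho`,
#'   `orders_diet_only`, `orders_availability_only`.
#' @export
rank_discordance <- function(profile, availability, stratum = NULL) {
  av <- as.data.frame(availability)
  stratum <- stratum %||% av$stratum[1]
  av <- av[av$stratum == stratum, , drop = FALSE]
  meta <- c("territory", "stratum", "prey_total", "hymenoptera_total",
            "pc1", "pc2")
  orders_av <- setdiff(names(av), meta)
  biomass <- colMeans(av[orders_av])
  shared <- intersect(profile$order, orders_av)
  if (!length(shared)) {
    stop_wrenlink("diet and availability share no orders",
                  "wrenlink_input_error")
  }
  fo <- profile$fo[match(shared, profile$order)]
  bm <- biomass[shared]
  diet_rank <- rank(-fo, ties.method = "average")
  avail_rank <- rank(-bm, ties.method = "average")
  half <- (length(shared) + 1) / 2
  flag <- ifelse(diet_rank <= half & avail_rank > half,
                 "high_diet_low_availability",
                 ifelse(diet_rank > half & avail_rank <= half,
                        "low_diet_high_availability", ""))
  tab <- data.frame(order = shared, fo = fo, mean_biomass = unname(bm),
                    diet_rank = diet_rank, availability_rank = avail_rank,
                    flag = flag, stringsAsFactors = FALSE)
  tab <- tab[order(tab$diet_rank), ]
  rownames(tab) <- NULL
  rho <- if (length(shared) >= 2 && stats::sd(diet_rank) > 0 &&
               stats::sd(avail_rank) > 0) {
    stats::cor(diet_rank, avail_rank, method = "spearman")
  } else NA_real_
  structure(list(table = tab, spearman_rho = rho, stratum = stratum,
                 orders_diet_only = setdiff(profile$order, orders_av),
                 orders_availability_only = setdiff(orders_av,
                                                    profile$order)),
            class = "rank_discordance")
}

#' @export
print.rank_discordance <- function(x, ...) {
  cat(sprintf("Diet vs availability ranking (%s stratum)\n", x$stratum))
  print(x$table, row.names = FALSE)
  cat(sprintf("  Spearman rho = %.3f\n", x$spearman_rho))
  if (length(x$orders_diet_only)) {
    cat("  diet only:", paste(x$orders_diet_only, collapse = ", "), "\n")
  }
  if (length(x$orders_availability_only)) {
    cat("  availability only:",
        paste(x$orders_availability_only, collapse = ", "), "\n")
  }
  invisible(x)
}
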