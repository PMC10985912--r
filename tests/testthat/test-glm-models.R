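test_that("binomial sign model recovers flat odds and rejects one condition", {
  rec <- data.frame(
    network_id = paste0("n", 1:10),
    condition = rep(c("snow_free", "snow_covered"), each = 5L),
    n_pos = 50L, n_neg = 50L, stringsAsFactors = FALSE)
  fit <- fit_sign_binomial(rec)
  expect_lt(abs(coef(fit$model)[2]), 1e-8)
  expect_equal(unname(fit$fitted_odds), c(1, 1), tolerance = 1e-6)

  expect_error(fit_sign_binomial(rec[rec$condition == "snow_free", ]),
               "both conditions")
})

test_that("binomial fit equals the disaggregated Bernoulli likelihood", {
  set.seed(81)
  rec <- data.frame(
    network_id = paste0("n", 1:8),
    condition = rep(c("snow_free", "snow_covered"), each = 4L),
    n_pos = rbinom(8, 100, c(rep(0.4, 4), rep(0.35, 4))),
    stringsAsFactors = FALSE)
  rec$n_neg <- 100L - rec$n_pos
  agg <- fit_sign_binomial(rec)
  long <- data.frame(
    condition = factor(rep(rec$condition, each = 100L),
                       levels = c("snow_free", "snow_covered")),
    y = unlist(lapply(seq_len(8), function(i) {
      rep(c(1L, 0L), c(rec$n_pos[i], rec$n_neg[i]))
    })))
  bern <- glm(y ~ condition, family = binomial(), data = long)
  expect_equal(unname(coef(agg$model)), unname(coef(bern)), tolerance = 1e-8)
})

test_that("complete separation triggers the flagged corrected refit", {
  rec <- data.frame(
    network_id = paste0("n", 1:6),
    condition = rep(c("snow_free", "snow_covered"), each = 3L),
    n_pos = c(30L, 28L, 25L, 0L, 0L, 0L),
    n_neg = c(0L, 0L, 0L, 30L, 28L, 25L), stringsAsFactors = FALSE)
  expect_warning(fit <- fit_sign_binomial(rec), "separation")
  expect_true(fit$separation_corrected)
  expect_true(all(is.finite(coef(fit$model))))
})

test_that("stepwise AIC keeps the intercept-only model on flat counts", {
  rec <- expand.grid(phylum = paste0("P", 1:4),
                     condition = c("snow_free", "snow_covered"),
                     rep = 1:6, stringsAsFactors = FALSE)
  rec$n_fb <- 10L
  fit <- fit_phylum_poisson(rec)
  # equal counts everywhere: AIC comparison oracle picks no terms
  start <- glm(n_fb ~ phylum + condition, poisson(), data = rec)
  null <- glm(n_fb ~ 1, poisson(), data = rec)
  expect_lt(AIC(null), AIC(start))
  expect_length(fit$selected_terms, 0L)
})

test_that("a planted phylum-by-condition rate shift is retained with CI", {
  set.seed(82)
  phyla <- paste0("P", 1:4)
  rec <- expand.grid(phylum = phyla,
                     condition = c("snow_free", "snow_covered"),
                     rep = 1:25, stringsAsFactors = FALSE)
  lam <- ifelse(rec$phylum == "P1" & rec$condition == "snow_covered", 20, 10)
  rec$n_fb <- rpois(nrow(rec), lam)
  fit <- fit_phylum_poisson(rec)
  expect_true("phylum:condition" %in% fit$selected_terms)
  rr <- phylum_rate_ratio(fit$model, "P1")
  expect_gt(rr[["upper"]], 2 * 0.8)
  expect_lt(rr[["lower"]], 2 * 1.25)
  expect_equal(unname(rr[["estimate"]]), 2, tolerance = 0.35)
})

test_that("poisson fitted means respect factor-level margins", {
  set.seed(83)
  rec <- expand.grid(phylum = paste0("P", 1:3),
                     condition = c("snow_free", "snow_covered"),
                     rep = 1:10, stringsAsFactors = FALSE)
  rec$n_fb <- rpois(nrow(rec), ifelse(rec$phylum == "P2", 15, 6))
  fit <- glm(n_fb ~ phylum + condition, poisson(), data = rec)
  for (ph in paste0("P", 1:3)) {
    rows <- rec$phylum == ph
    expect_equal(sum(fitted(fit)[rows]), sum(rec$n_fb[rows]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate phylum records are rejected or dropped", {
  rec <- expand.grid(phylum = c("P1", "P2"), condition = "snow_free",
                     rep = 1:3, stringsAsFactors = FALSE)
  rec$n_fb <- 5L
  expect_error(fit_phylum_poisson(rec), "both conditions")

  rec2 <- expand.grid(phylum = c("P1", "P2", "P3"),
                      condition = c("snow_free", "snow_covered"),
                      rep = 1:3, stringsAsFactors = FALSE)
  rec2$n_fb <- ifelse(rec2$phylum == "P3", 0L, 4L)
  fit2 <- fit_phylum_poisson(rec2)
  expect_false("P3" %in% fit2$estimates$phylum)

  rec3 <- rec2; rec3$n_fb <- 0L
  expect_error(fit_phylum_poisson(rec3), "zero")
})

test_that("stepwise_aic returns the sole candidate unchanged", {
  d <- data.frame(y = rpois(20, 5), x = rnorm(20))
  fit <- glm(y ~ 1, poisson(), data = d)
  sel <- stepwise_aic(fit, lower = ~1, upper = ~1)
  expect_equal(deviance(sel), deviance(fit))
})

test_that("phylum counts are extracted per network and zero-filled", {
  tax <- data.frame(asv_id = c("F01", "F02", "B01", "B02"),
                    phylum = c("Asco", "Basidio", "Proteo", "Acido"),
                    stringsAsFactors = FALSE)
  n1 <- toy_network(edge_df(c("F01", "F01", "F02"), c("B01", "B02", "B01")),
                    condition = "snow_free")
  n2 <- toy_network(edge_df("F01", "B01"), condition = "snow_covered")
  recs <- phylum_freq_records(list(snow_free = list(n1),
                                   snow_covered = list(n2)), tax)
  expect_equal(recs$n_fb[recs$phylum == "Asco" &
                           recs$condition == "snow_free"], 2L)
  expect_equal(recs$n_fb[recs$phylum == "Basidio" &
                           recs$condition == "snow_covered"], 0L)
  # per-network totals equal each network's fb count
  expect_equal(sum(recs$n_fb[recs$condition == "snow_free"]), 3L)
  expect_equal(sum(recs$n_fb[recs$condition == "snow_covered"]), 1L)
})
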