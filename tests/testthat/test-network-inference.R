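test_that("joint CLR rows sum to zero and match hand arithmetic", {
  f <- toy_counts(rbind(c(0, 3), c(2, 2), c(5, 1)), prefix = "F")
  b <- toy_counts(rbind(c(1, 1), c(4, 0), c(2, 2)), prefix = "B")
  clr <- joint_clr(f, b)
  expect_equal(unname(rowSums(clr)), rep(0, 3), tolerance = 1e-8)
  expect_identical(attr(clr, "kingdom"), rep(c("fungi", "bacteria"), each = 2))

  # raw-count variant, counts (0, 3): x = (ln1 - m, ln4 - m),
  # m = (ln1 + ln4)/2
  one <- joint_clr(toy_counts(matrix(0L, 1, 1), prefix = "F"),
                   toy_counts(matrix(3L, 1, 1), prefix = "B"),
                   normalize = FALSE)
  expect_equal(unname(one[1, ]), c(-log(4) / 2, log(4) / 2), tolerance = 1e-12)
  expect_equal(unname(one[1, 1]), -0.6931, tolerance = 1e-4)

  # constant count row -> all-zero CLR row (raw variant)
  const <- joint_clr(toy_counts(matrix(7L, 1, 2), prefix = "F"),
                     toy_counts(matrix(7L, 1, 3), prefix = "B"),
                     normalize = FALSE)
  expect_equal(unname(const[1, ]), rep(0, 5))
  # the depth-unbiased default also has zero row sums there
  constn <- joint_clr(toy_counts(matrix(7L, 1, 2), prefix = "F"),
                      toy_counts(matrix(7L, 1, 3), prefix = "B"))
  expect_equal(sum(constn[1, ]), 0, tolerance = 1e-12)

  # per-kingdom variant centres within kingdom
  pk <- joint_clr(f, b, per_kingdom = TRUE)
  expect_equal(unname(rowSums(pk[, 1:2])), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(rowSums(pk[, 3:4])), rep(0, 3), tolerance = 1e-8)

  b2 <- b; rownames(b2) <- c("S1", "S2", "X3")
  expect_error(joint_clr(f, b2), "same samples")
})

test_that("mb_fit agrees with the glmnet lasso on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(61)
  n <- 40L; p <- 12L
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- x[, 1] * 0.9 + rnorm(n, sd = 0.3)
  colnames(x) <- paste0("V", seq_len(p))
  xs <- fbnet:::standardize_cols(x)
  for (lambda in c(0.3, 0.1, 0.05)) {
    B <- mb_fit(x, lambda)
    for (j in c(1L, 2L, 7L)) {
      g <- glmnet::glmnet(xs[, -j], xs[, j], lambda = lambda,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
      ref <- rep(0, p); ref[-j] <- as.numeric(g$beta)
      expect_equal(unname(B[, j]), ref, tolerance = 1e-3)
    }
  }
})

test_that("mb_fit shrinks to zero above lambda_max and is order invariant", {
  set.seed(62)
  x <- matrix(rnorm(30 * 8), 30, 8)
  colnames(x) <- paste0("V", 1:8)
  xs <- fbnet:::standardize_cols(x)
  lmax <- max(abs((crossprod(xs) / nrow(xs))[upper.tri(diag(8))]))
  expect_true(all(mb_fit(x, lmax * 1.01) == 0))

  B <- mb_fit(x, lmax * 0.3)
  perm <- sample(nrow(x))
  B2 <- mb_fit(x[perm, ], lmax * 0.3)
  expect_equal(B, B2, tolerance = 1e-6)
  expect_error(mb_fit(x, -0.1), ">= 0")
  expect_error(mb_fit(x[1:2, ], 0.1), ">= 3 samples")
})

test_that("two equal features select each other at small lambda", {
  set.seed(63)
  n <- 50L
  x1 <- rnorm(n)
  x <- cbind(x1, x1, matrix(rnorm(n * 4), n))
  colnames(x) <- paste0("V", 1:6)
  B <- mb_fit(x, 0.05)
  expect_true(B[1, 2] != 0 && B[2, 1] != 0)
  # closed-form single-predictor lasso: beta = S(r, lambda) with r ~ 1
  xs <- fbnet:::standardize_cols(x)
  r <- mean(xs[, 1] * xs[, 2])
  expect_equal(B[1, 2], r - 0.05, tolerance = 0.05)
})

test_that("lasso path is monotone for the single-predictor closed form", {
  set.seed(64)
  n <- 60L
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = 0.6)
  x <- cbind(x1, x2); colnames(x) <- c("V1", "V2")
  xs <- fbnet:::standardize_cols(x)
  r <- abs(mean(xs[, 1] * xs[, 2]))
  lams <- seq(r * 1.1, r * 0.05, length.out = 8)
  sizes <- vapply(lams, function(l) sum(mb_fit(x, l) != 0), integer(1L))
  expect_true(all(diff(sizes) >= 0))
  # exact closed form: S(r, lambda)
  B <- mb_fit(x, r / 2)
  expect_equal(abs(B[1, 2]), r - r / 2, tolerance = 1e-4)
})

test_that("stars_select is deterministic and flat on empty graphs", {
  set.seed(65)
  x <- matrix(rnorm(20 * 6), 20, 6)
  colnames(x) <- paste0("V", 1:6)
  s1 <- suppressWarnings(stars_select(x, stars_control(n_subsamples = 8), seed = 99))
  s2 <- suppressWarnings(stars_select(x, stars_control(n_subsamples = 8), seed = 99))
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$instability_path, s2$instability_path)

  # constant features admit no edges: the graph is empty at every lambda
  # and the instability is identically zero
  const <- matrix(rep(c(1, 2, 3, 4), each = 20), 20, 4)
  colnames(const) <- paste0("C", 1:4)
  s3 <- stars_select(const, stars_control(n_subsamples = 6, n_lambda = 5),
                     seed = 1)
  expect_true(all(s3$instability_path$instability == 0))
})

test_that("refit_and_weight applies the symmetrisation rule and drops orphans", {
  # hand-made CLR-like matrix with one strong pair among 6 features
  set.seed(66)
  n <- 60L
  a <- rnorm(n)
  x <- cbind(a, a * 0.9 + rnorm(n, sd = 0.4), matrix(rnorm(n * 4), n))
  colnames(x) <- c("F1", "B1", "F2", "B2", "B3", "B4")
  attr(x, "kingdom") <- c("fungi", "bacteria", "fungi", rep("bacteria", 3))
  net <- refit_and_weight(x, lambda = 0.25)
  expect_s3_class(net, "association_network")
  expect_true(nrow(net$edges) >= 1L)
  k <- edge_key(net$edges$a, net$edges$b)
  expect_true(edge_key("F1", "B1") %in% k)
  # every retained node has an incident edge (orphans removed)
  expect_setequal(net$nodes$id, unique(c(net$edges$a, net$edges$b)))
  # weights are the larger-magnitude directed coefficient
  B <- mb_fit(x, 0.25)
  i <- match("B1", colnames(x)); j <- match("F1", colnames(x))
  expect_equal(net$edges$weight[k == edge_key("F1", "B1")],
               c(B[i, j], B[j, i])[which.max(abs(c(B[i, j], B[j, i])))])
  expect_true(all(net$edges$sign == ifelse(net$edges$weight > 0, "+", "-")))

  # empty selection gives an empty network
  net0 <- refit_and_weight(x, lambda = 10)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(nrow(net0$nodes), 0L)
})

test_that("a planted pair is recovered by the full per-condition inference", {
  sim <- simulate_communities(small_sim_config(seed = 10L))
  grid <- build_grid(sim$fungi, sim$bacteria, t_fungal = 3L, t_bacterial = 5L)
  nets <- suppressMessages(
    infer_condition_networks(grid[[1]], sim$metadata,
                             control = stars_control(n_subsamples = 10),
                             seed = 3))
  expect_named(nets, c("snow_free", "snow_covered"))
  # the strong "both"-condition pair F0001-B0001 (rho = 0.8) is present
  keys_sf <- edge_key(nets$snow_free$edges$a, nets$snow_free$edges$b)
  keys_sc <- edge_key(nets$snow_covered$edges$a, nets$snow_covered$edges$b)
  expect_true(edge_key("F0001", "B0001") %in% union(keys_sf, keys_sc))

  meta1 <- sim$metadata
  meta1$condition <- factor("snow_free", levels = levels(meta1$condition))
  expect_error(
    infer_condition_networks(grid[[1]], meta1, seed = 1),
    "condition absent|>= 4 samples")
})
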