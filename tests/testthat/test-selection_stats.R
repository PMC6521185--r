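test_that("expected ENc closed form", {
  expect_equal(expected_enc(0.5), 60.5)
  # s -> 0+ limit is 31
  expect_equal(expected_enc(1e-9), 31, tolerance = 1e-6)
  expect_error(expected_enc(0), "inside")
  expect_error(expected_enc(1.2), "inside")
  # independent re-evaluation of the closed form on a grid
  oracle <- function(s) 2 + s + 29 / (s * s + (1 - s) * (1 - s))
  s <- c(0.38, 0.1, 0.25, 0.62, 0.9)
  expect_equal(expected_enc(s), oracle(s))
})

test_that("enc_gc3_data pairs records with the expected curve", {
  sim <- generate_set(synthetic_spec(c(g = 20), n_codons = 150,
                                     model = model_mutation_pressure(),
                                     seed = 5))
  d <- enc_gc3_data(sim$set)
  expect_identical(nrow(d$points), 20L)
  expect_true(all(d$curve$GC3 > 0 & d$curve$GC3 < 1))
  expect_equal(d$points$expected, expected_enc(d$points$GC3))
})

test_that("expected curve is an upper envelope under pure GC3 bias", {
  # Long sequences: at coat-protein length (223 codons) Wright's estimator
  # has a known upward small-sample bias, so the envelope is a property of
  # the frequency limit, checked here at 5000 codons.
  sim <- generate_set(synthetic_spec(
    c(s = 30), n_codons = 5000,
    model = model_third_position_selection(c(0.25, 0.65)), seed = 14))
  d <- suppressWarnings(enc_gc3_data(sim$set))
  expect_true(all(d$points$ENc <= d$points$expected + 2.0))
})

test_that("neutrality regression closed forms and degeneracies", {
  gc3 <- seq(0.2, 0.6, length.out = 10)
  fit <- neutrality_regression(gc3, gc3)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)

  fit0 <- neutrality_regression(rep(0.44, 10), gc3)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)

  expect_error(neutrality_regression(gc3, rep(0.4, 10)), "zero variance")
  expect_error(neutrality_regression(c(1, 2), c(1, 2)), "at least 3")

  # R^2 = r^2 and slope * sd_x / sd_y = r
  set.seed(8)
  x <- stats::runif(50); y <- 0.3 * x + stats::rnorm(50, 0, 0.05)
  fit <- neutrality_regression(y, x)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
  expect_equal(fit$slope * stats::sd(x) / stats::sd(y), fit$pearson_r)
})

test_that("neutrality slope recovers the generating regime", {
  # genome-wide mutation pressure: slope near 1
  mut <- generate_set(synthetic_spec(
    c(m = 200), n_codons = 223,
    model = model_mutation_pressure(c(0.25, 0.65)), seed = 71))
  prof <- t(vapply(mut$set, composition_profile,
                   composition_profile(mut$set[[1]])))
  fit_m <- neutrality_regression(prof[, "GC12"], prof[, "GC3"])
  expect_gt(fit_m$slope, 0.8)
  expect_lt(fit_m$slope, 1.2)

  # third-position selection: slope near 0
  sel <- generate_set(synthetic_spec(
    c(s = 200), n_codons = 223,
    model = model_third_position_selection(c(0.25, 0.65)), seed = 72))
  prof <- t(vapply(sel$set, composition_profile,
                   composition_profile(sel$set[[1]])))
  fit_s <- neutrality_regression(prof[, "GC12"], prof[, "GC3"])
  expect_gt(fit_s$slope, -0.15)
  expect_lt(fit_s$slope, 0.15)
})

test_that("correlation matrix flags and structural correlations", {
  x <- seq_len(30)
  m <- data.frame(x = x, y = 2 * x + 1)
  cm <- correlation_matrix(m)
  expect_equal(cm$r["x", "y"], 1)
  expect_identical(cm$flag["x", "y"], "**")

  # complementary composition pairs are perfectly anti-correlated
  sim <- generate_set(synthetic_spec(c(g = 30), n_codons = 120,
                                     model = model_mutation_pressure(),
                                     seed = 3))
  it <- index_table(sim$set)
  cm <- correlation_matrix(it)
  expect_equal(cm$r["GU", "AC"], -1)
  expect_true(isSymmetric(cm$r))
  expect_true(all(diag(cm$r) == 1))

  # independent columns: small r, not significant at the 0.01 level
  set.seed(19)
  ind <- data.frame(a = stats::rnorm(200), b = stats::rnorm(200))
  cm <- correlation_matrix(ind)
  expect_lt(abs(cm$r["a", "b"]), 0.2)
  expect_identical(cm$flag["a", "b"] %in% c("", "*"), TRUE)

  # constant column -> missing correlation, no crash
  cc <- correlation_matrix(data.frame(a = stats::rnorm(10), b = rep(1, 10)))
  expect_true(is.na(cc$r["a", "b"]))
})

test_that("one-way ANOVA closed forms and invariances", {
  res0 <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)

  # hand-computed sums of squares: SSB = 150 (df 1), MSW = 1 (df 4)
  v <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  res <- one_way_anova(v, g)
  expect_equal(res$F, 150)
  expect_lt(res$p, 0.01)
  expect_equal(as.vector(res$group_means), c(2, 12))

  # invariant to adding a constant
  res_shift <- one_way_anova(v + 100, g)
  expect_equal(res_shift$F, res$F)

  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")), "fewer than 2")
  expect_error(one_way_anova(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ANOVA p-values are uniform under a shuffled null", {
  set.seed(123)
  pooled <- stats::rnorm(60)
  pvals <- replicate(500, {
    one_way_anova(pooled, sample(rep(c("a", "b", "c"), each = 20)))$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
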