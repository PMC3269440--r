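two_batch_sheet <- function(n_per_batch, group = NULL) {
  n <- 2 * n_per_batch
  toy_sheet(sprintf("s%02d", 1:n),
            rep(c("b1", "b2"), each = n_per_batch),
            group = if (is.null(group)) NA_character_ else
              rep_len(group, n))
}

test_that("null batches give near-zero additive and unit scale estimates", {
  set.seed(71)
  G <- 3000
  sh <- two_batch_sheet(6)
  m <- toy_matrix(matrix(rnorm(G * 12, 8, 1), G, 12),
                  sample_ids = sh$sample_id)
  fit <- combat_fit(m, sh, "batch")
  expect_lt(abs(mean(fit$gamma_star)), 0.02)
  # the pooled SD divides by N while batch variances use n_i - 1, so the
  # scale estimates centre at N / (N - n_batches), not exactly 1
  expect_lt(abs(mean(fit$delta2_star) - 12 / 10), 0.1)
  out <- combat_apply(m, fit)
  # correction is mild when there is nothing to correct
  expect_lt(sqrt(mean((out$values - m$values)^2)), 0.5)
})

test_that("injected mean shifts are recovered and removed", {
  set.seed(73)
  G <- 2000
  sh <- two_batch_sheet(6)
  base <- matrix(rnorm(G * 12, 8, 1), G, 12)
  shift <- rep(c(-0.5, 0.5), each = 6)
  m <- toy_matrix(base + rep(shift, each = G), sample_ids = sh$sample_id)
  fit <- combat_fit(m, sh, "batch")
  # additive effect on the data scale: sigma_g * gamma*_ig
  est <- fit$gamma_star * sqrt(fit$var_pooled)
  expect_lt(abs(mean(est[, "b1"]) - (-0.5)) / 0.5, 0.05)
  expect_lt(abs(mean(est[, "b2"]) - 0.5) / 0.5, 0.05)

  # the systematic between-batch variance component (which discounts the
  # batch-mean sampling noise), pooled across probes, is eliminated
  out <- combat_apply(m, fit)
  ms <- nested_model_spec("batch")
  comp_pre <- batchscope:::fit_nested_mom_matrix(m$values, sh, ms)
  comp_post <- batchscope:::fit_nested_mom_matrix(out$values, sh, ms)
  pooled <- function(comp) sqrt(max(mean(comp$variance_raw[, "batch"]), 0))
  expect_lt(pooled(comp_post), 0.05 * pooled(comp_pre))
})

test_that("inverse-gamma hyperprior recovery by moment matching", {
  set.seed(79)
  lambda <- 5; theta <- 4
  x <- 1 / rgamma(10000, shape = lambda, rate = theta)
  ig <- batchscope:::ig_moment_match(mean(x), var(x))
  expect_lt(abs(ig$lambda - lambda) / lambda, 0.1)
  expect_lt(abs(ig$theta - theta) / theta, 0.1)
  # and the matched prior reproduces the sample moments exactly
  expect_equal(ig$theta / (ig$lambda - 1), mean(x))
  expect_equal(ig$theta^2 / ((ig$lambda - 1)^2 * (ig$lambda - 2)), var(x))
})

test_that("a single-batch model reduces to the identity", {
  set.seed(83)
  sh <- toy_sheet(sprintf("s%d", 1:6), rep("b1", 6))
  m <- toy_matrix(matrix(rnorm(300), 50, 6), sample_ids = sh$sample_id)
  fit <- combat_fit(m, sh, "batch")
  out <- combat_apply(m, fit)
  expect_lt(max(abs(out$values - m$values)), 1e-9)
})

test_that("correction is nearly idempotent", {
  set.seed(89)
  G <- 800
  sh <- two_batch_sheet(6)
  m <- toy_matrix(matrix(rnorm(G * 12, 8, 1), G, 12) +
                    outer(rnorm(G, 0, 0.4), rep(c(0, 1), each = 6)),
                  sample_ids = sh$sample_id)
  once <- combat_apply(m, combat_fit(m, sh, "batch"))
  twice <- combat_apply(once, combat_fit(once, sh, "batch"))
  # a second pass only nibbles at batch-mean sampling noise: its changes
  # are well below the first correction's
  rms1 <- sqrt(mean((once$values - m$values)^2))
  rms2 <- sqrt(mean((twice$values - once$values)^2))
  expect_lt(rms2, 0.5 * rms1)
  # and the pooled systematic batch component stays at zero
  ms <- nested_model_spec("batch")
  comp <- batchscope:::fit_nested_mom_matrix(twice$values, sh, ms)
  expect_lt(sqrt(max(mean(comp$variance_raw[, "batch"]), 0)), 0.02)
})

test_that("matches the reference empirical-Bayes implementation", {
  set.seed(97)
  G <- 400
  batch <- rep(c("b1", "b2", "b3"), times = c(4, 5, 6))
  group <- rep_len(c("g1", "g2"), 15)
  sh <- toy_sheet(sprintf("s%02d", 1:15), batch, group = group)
  Y <- matrix(rnorm(G * 15, 8, 1), G, 15) +
    outer(rnorm(G, 0, 0.5), as.integer(factor(batch))) +
    outer(rnorm(G, 0, 0.5), as.integer(factor(group)))
  m <- toy_matrix(Y, sample_ids = sh$sample_id)
  out <- combat_apply(m, combat_fit(m, sh, "batch", covariates = "group"))
  ref <- sva::ComBat(dat = m$values, batch = factor(batch),
                     mod = model.matrix(~ factor(group)), par.prior = TRUE)
  expect_lt(max(abs(out$values - ref)), 1e-4)
})

test_that("mean centring re-centres every batch at the grand mean", {
  sh <- two_batch_sheet(2)
  m <- toy_matrix(matrix(c(1, 3, 3, 5), 1), sample_ids = sh$sample_id)
  out <- mean_center(m, sh, "batch")
  expect_equal(unname(out$values), matrix(c(2, 4, 2, 4), 1))

  one_batch <- toy_sheet(sprintf("s%d", 1:4), rep("b1", 4))
  m2 <- toy_matrix(matrix(rnorm(8), 2), sample_ids = one_batch$sample_id)
  expect_equal(mean_center(m2, one_batch, "batch")$values, m2$values)
})

test_that("unshrunk mean-only correction equals mean centring", {
  set.seed(101)
  sh <- two_batch_sheet(4)
  m <- toy_matrix(matrix(rnorm(200 * 8, 8, 1), 200, 8),
                  sample_ids = sh$sample_id)
  ebs <- combat_apply(m, combat_fit(m, sh, "batch", shrink = FALSE,
                                    mean_only = TRUE))
  mc <- mean_center(m, sh, "batch")
  expect_lt(max(abs(ebs$values - mc$values)), 1e-6)
})

test_that("degenerate and confounded designs are refused", {
  sh <- toy_sheet(sprintf("s%d", 1:5), c("b1", "b1", "b1", "b1", "b2"))
  m <- toy_matrix(matrix(rnorm(50), 10, 5), sample_ids = sh$sample_id)
  expect_error(combat_fit(m, sh, "batch"), "single sample")

  # group fully confounded with batch: fitting must not silently proceed
  sh2 <- toy_sheet(sprintf("s%d", 1:8), rep(c("b1", "b2"), each = 4),
                   group = rep(c("g1", "g2"), each = 4))
  m2 <- toy_matrix(matrix(rnorm(400), 50, 8), sample_ids = sh2$sample_id)
  expect_error(combat_fit(m2, sh2, "batch", covariates = "group"),
               "confounded")

  # sample with unknown batch at apply time
  fit <- combat_fit(m2, sh2, "batch")
  m3 <- toy_matrix(matrix(rnorm(50), 50, 1), sample_ids = "zz")
  expect_error(combat_apply(m3, fit), "unknown batch")
})

test_that("group fold changes survive correction when not confounded", {
  set.seed(103)
  spec <- design_spec(n_probes = 800, nesting = c(run = 2, chip = 2,
                                                  array = 6),
                      level_sd = c(run = 0.4, chip = 0.3),
                      residual_sd = 0.15,
                      group_design = list(groups = c("pre", "post"),
                                          frac_differential = 0.15,
                                          effect_sd = 1),
                      duplicate_plan = 0,
                      calibrators = list(generic_per_chip = 0,
                                         pooled_per_chip = 0),
                      seed = 103)
  sim <- simulate_experiment(spec)
  corr <- combat_correct(sim$expression, sim$samples, "chip",
                         covariates = "group")
  de_pre <- de_test(sim$expression, sim$samples, fc_min = 1, p_max = 1,
                    groups = c("pre", "post"))
  de_post <- de_test(corr, sim$samples, fc_min = 1, p_max = 1,
                     groups = c("pre", "post"))
  big <- abs(sim$truth$group_effects[, "post"]) >= 1
  rel <- abs(de_post$lfc[big] - de_pre$lfc[big]) /
    pmax(abs(de_pre$lfc[big]), 0.5)
  expect_lt(mean(rel), 0.1)
})
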