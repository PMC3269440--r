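test_that("EMS solves the hand-computable nested ANOVA", {
  # 2 groups of 2 with values {0,0} and {2,2}: MS_between = 4, MS_within = 0
  sh <- toy_sheet(c("a", "b", "c", "d"), c("B1", "B1", "B2", "B2"))
  fit <- fit_nested_mom(setNames(c(0, 0, 2, 2), sh$sample_id), sh,
                        nested_model_spec("batch"))
  expect_equal(fit$variance, c(batch = 2, residual = 0))

  # all observations equal -> all components zero
  flat <- fit_nested_mom(setNames(rep(1, 4), sh$sample_id), sh,
                         nested_model_spec("batch"))
  expect_equal(flat$variance, c(batch = 0, residual = 0))

  # unbalanced designs are refused and redirected
  sh_u <- toy_sheet(c("a", "b", "c"), c("B1", "B1", "B2"))
  expect_error(fit_nested_mom(setNames(1:3, sh_u$sample_id), sh_u,
                              nested_model_spec("batch")),
               "fit_nested_reml")
})

test_that("EMS estimates are unbiased for known components", {
  set.seed(29)
  G <- 5000
  truth <- c(experiment = 0.3, run = 0.15, chip = 0.1)
  d <- draw_nested(G, c(experiment = 3, run = 2, chip = 2, array = 2),
                   truth, 0.2)
  fit <- batchscope:::fit_nested_mom_matrix(d$m$values, d$sheet,
                                      nested_model_spec(names(truth)))
  # the raw (untruncated) EMS solutions are unbiased for the components
  mean_var <- colMeans(fit$variance_raw)
  for (lv in names(truth))
    expect_lt(abs(mean_var[[lv]] - truth[[lv]]^2) / truth[[lv]]^2, 0.05)
  expect_lt(abs(mean_var[["residual"]] - 0.04) / 0.04, 0.05)
  # truncation at zero only ever raises the reported components
  expect_true(all(fit$variance >= fit$variance_raw))
})

test_that("REML equals EMS on balanced designs with interior solutions", {
  set.seed(37)
  G <- 100
  d <- draw_nested(G, c(experiment = 3, run = 2, chip = 2, array = 2),
                   c(experiment = 0.3, run = 0.15, chip = 0.1), 0.2)
  ms <- nested_model_spec(c("experiment", "run", "chip"))
  mom <- batchscope:::fit_nested_mom_matrix(d$m$values, d$sheet, ms)
  interior <- apply(mom$variance[, 1:3] >
                      0.01 * rowSums(mom$variance), 1, all)
  expect_gt(sum(interior), 10)
  for (g in which(interior)[1:10]) {
    reml <- fit_nested_reml(d$m$values[g, ], d$sheet, ms)
    expect_true(reml$converged)
    expect_equal(unname(reml$variance), unname(mom$variance[g, ]),
                 tolerance = 1e-6)
  }
})

test_that("REML matches the nlme reference on unbalanced data", {
  set.seed(9)
  d <- draw_nested(4, c(experiment = 3, run = 2, chip = 2, array = 3),
                   c(experiment = 0.4, run = 0.3, chip = 0.2), 0.3)
  keep <- sort(sample(ncol(d$m$values), ncol(d$m$values) - 7))
  m <- d$m[, keep]
  ms <- nested_model_spec(c("experiment", "run", "chip"))
  for (g in 1:4) {
    y <- m$values[g, ]
    fit <- fit_nested_reml(y, d$sheet, ms)
    df <- data.frame(y = y,
                     d$sheet[match(names(y), d$sheet$sample_id),
                             c("experiment", "run", "chip")])
    lfit <- nlme::lme(y ~ 1, random = ~ 1 | experiment / run / chip,
                      data = df,
                      control = nlme::lmeControl(opt = "optim",
                                                 returnObject = TRUE))
    vc <- suppressWarnings(as.numeric(nlme::VarCorr(lfit)[c(2, 4, 6, 7), 1]))
    expect_lt(max(abs(unname(fit$variance) - vc)), 5e-4)
    expect_gte(fit$loglik, as.numeric(stats::logLik(lfit)) - 1e-4)
  }
})

test_that("REML finds the zero boundary when a component is absent", {
  set.seed(53)
  G <- 100
  d <- draw_nested(G, c(experiment = 3, run = 2, chip = 2, array = 2),
                   c(experiment = 0.3, run = 0, chip = 0.1), 0.2)
  ms <- nested_model_spec(c("experiment", "run", "chip"))
  at_zero <- vapply(seq_len(G), function(g) {
    fit <- fit_nested_reml(d$m$values[g, ], d$sheet, ms)
    fit$sd[["run"]] <= 1e-6
  }, logical(1))
  expect_gte(mean(at_zero), 0.5)

  # flat probe: all components zero, converged
  sh <- toy_sheet(sprintf("s%d", 1:4), c("B1", "B1", "B2", "B2"))
  flat <- fit_nested_reml(setNames(rep(2, 4), sh$sample_id), sh,
                          nested_model_spec("batch"))
  expect_true(flat$converged)
  expect_equal(unname(flat$variance), c(0, 0))
})

test_that("levels with a single unit are reported as inestimable", {
  set.seed(61)
  d <- draw_nested(2, c(experiment = 1, run = 2, chip = 2, array = 2),
                   c(experiment = 0, run = 0.2, chip = 0.1), 0.2)
  fit <- fit_nested_reml(d$m$values[1, ], d$sheet,
                         nested_model_spec(c("experiment", "run", "chip")))
  expect_true(is.na(fit$variance[["experiment"]]))
  expect_false(anyNA(fit$variance[c("run", "chip", "residual")]))
})

test_that("decompose_variance summarises probes and handles edge cases", {
  set.seed(43)
  d <- draw_nested(80, c(experiment = 3, run = 2, chip = 2, array = 2),
                   c(experiment = 0.3, run = 0.15, chip = 0.1), 0.2)
  dec <- decompose_variance(d$m, d$sheet,
                            nested_model_spec(c("experiment", "run", "chip")))
  expect_equal(sum(dec$summary$pct_contribution), 100, tolerance = 1e-9)
  expect_true(all(dec$per_probe$converged))

  # no random levels: residual equals the SD about the fixed-effect fit
  sh <- nested_sheet(c(run = 2, array = 4), group = c("a", "b"))
  y <- rnorm(8)
  m <- toy_matrix(matrix(y, 1), sample_ids = sh$sample_id)
  dec0 <- decompose_variance(m, sh,
                             nested_model_spec(character(0),
                                               fixed_factor = "group"))
  oracle <- summary(lm(y ~ sh$group))$sigma
  expect_equal(dec0$per_probe$residual, oracle)

  # a zero-variance probe is flagged, not fatal
  d$m$values[5, ] <- 3
  dec2 <- decompose_variance(d$m, d$sheet,
                             nested_model_spec(c("experiment", "run",
                                                 "chip")))
  expect_identical(dec2$per_probe$flag[5], "zero_variance")
  expect_equal(sum(dec2$summary$pct_contribution), 100, tolerance = 1e-9)
})

test_that("fixed biological effects are removed before decomposition", {
  set.seed(47)
  sh <- nested_sheet(c(experiment = 3, run = 2, chip = 2, array = 2),
                     group = c("a", "b"))
  d <- draw_nested(60, c(experiment = 3, run = 2, chip = 2, array = 2),
                   c(experiment = 0.3, run = 0.15, chip = 0.1), 0.2,
                   group_effect = 2, sheet = sh)
  ms_fixed <- nested_model_spec(c("experiment", "run", "chip"),
                                fixed_factor = "group")
  dec <- decompose_variance(d$m, sh, ms_fixed)
  # residual must reflect the 0.2 noise, not the group difference
  expect_lt(sqrt(mean(dec$per_probe$residual^2)), 0.3)
  # and REML agrees with the group-centred EMS fit
  mom <- fit_nested_mom(d$m$values[1, ], sh, ms_fixed)
  reml <- fit_nested_reml(d$m$values[1, ], sh, ms_fixed)
  interior <- all(mom$variance[1:3] > 0.01 * sum(mom$variance))
  if (interior)
    expect_equal(unname(reml$variance), unname(mom$variance),
                 tolerance = 1e-6)
})

test_that("component errors shrink as the design grows", {
  set.seed(59)
  sizes <- c(4, 8, 16)
  err <- vapply(sizes, function(ne) {
    d <- draw_nested(400, c(experiment = ne, run = 2, array = 2),
                     c(experiment = 0.3, run = 0.15), 0.2)
    fit <- batchscope:::fit_nested_mom_matrix(d$m$values, d$sheet,
                                        nested_model_spec(c("experiment",
                                                            "run")))
    mean(abs(fit$variance[, "experiment"] - 0.09) / 0.09)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
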