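dup_sheet <- function() {
  # 2 runs x 2 samples; one duplicate pair across runs plus controls
  df <- data.frame(
    sample_id = c("d1a", "d1b", "u1", "u2", "q1", "q2"),
    role = c("biological", "biological", "generic_control",
             "generic_control", "pooled_control", "pooled_control"),
    group = c("pre", "pre", NA, NA, NA, NA),
    duplicate_id = c("dup1", "dup1", "generic", "generic", "pool", "pool"),
    run = c("R1", "R2", "R1", "R2", "R1", "R2"),
    stringsAsFactors = FALSE)
  sample_sheet(df, "run")
}

test_that("batch shifts are oriented differences across batch pairs", {
  sh <- dup_sheet()
  v <- matrix(5, 4, 6, dimnames = list(sprintf("p%d", 1:4), sh$sample_id))
  v[, "d1b"] <- v[, "d1a"] + 1   # duplicate shifted by +1 in R2
  m <- expression_matrix(v)
  shifts <- batch_shifts(m, sh, "run")
  expect_setequal(shifts$pairs$kind,
                  c("sample_duplicate", "generic_control", "pooled_control"))
  dup <- shifts$pairs$kind == "sample_duplicate"
  expect_equal(unname(shifts$delta[, dup]), rep(1, 4))
  expect_equal(shifts$pairs$from[dup], "R1")  # lexicographic orientation
  ctl <- shifts$pairs$kind == "generic_control"
  expect_equal(unname(shifts$delta[, ctl]), rep(0, 4))
})

test_that("duplicate series handling: same-batch skips, >2 enumerations", {
  df <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "b3"),
    role = "biological", group = NA_character_,
    duplicate_id = c("same", "same", "tri", "tri", "tri"),
    run = c("R1", "R1", "R1", "R2", "R3"),
    stringsAsFactors = FALSE)
  sh <- sample_sheet(df, "run")
  m <- toy_matrix(matrix(rnorm(10), 2, 5), sample_ids = df$sample_id)
  expect_warning(shifts <- batch_shifts(m, sh, "run"), "same")
  # the triple yields all three cross-batch pairings
  expect_equal(sum(shifts$pairs$kind == "sample_duplicate"), 3L)
})

test_that("duplicate shifts track the realized batch effects", {
  spec <- design_spec(n_probes = 1500, nesting = c(run = 2, chip = 2,
                                                   array = 4),
                      level_sd = c(run = 0.3, chip = 0.15),
                      residual_sd = 0.1, duplicate_plan = 4,
                      duplicate_level = "run",
                      calibrators = list(generic_per_chip = 0,
                                         pooled_per_chip = 0),
                      expression_coupling = 0, seed = 107)
  sim <- simulate_experiment(spec)
  shifts <- batch_shifts(sim$expression, sim$samples, "run")
  tr <- sim$truth
  for (k in seq_len(nrow(shifts$pairs))) {
    p <- shifts$pairs[k, ]
    true_diff <- tr$batch_shift[, p$sample_to] - tr$batch_shift[, p$sample_from]
    resid <- shifts$delta[, k] - true_diff
    # residual difference is the two arrays' own noise: sd ~ sqrt(2)*0.1
    expect_lt(abs(mean(resid)), 4 * sqrt(2) * 0.1 / sqrt(1500))
    expect_lt(abs(sd(resid) - sqrt(2) * 0.1), 0.03)
  }
})

test_that("fidelity is 100 for identical shifts and ~0 for independent ones", {
  set.seed(109)
  delta <- rnorm(10000, 0, 0.5)
  fid <- calibrator_fidelity(delta, delta)
  expect_equal(unname(fid), rep(100, 4))
  indep <- calibrator_fidelity(rnorm(10000, 0, 0.5), delta,
                               magnitude_bins = 0)
  expect_lt(abs(indep[["gt_0"]]), 5)
  # empty bins are absent, not zero
  small <- calibrator_fidelity(rnorm(5), rnorm(5, 0, 0.01),
                               magnitude_bins = c(0, 3))
  expect_true(is.na(small[["gt_3"]]))
  expect_error(calibrator_fidelity(rnorm(3), rnorm(4)), "universe")
})

test_that("fidelity grows with shift magnitude under expression coupling", {
  gains <- vapply(1:10, function(s) {
    spec <- design_spec(n_probes = 2000, nesting = c(run = 2, chip = 4,
                                                     array = 6),
                        level_sd = c(run = 0.3, chip = 0.15),
                        residual_sd = 0.1, duplicate_plan = 6,
                        duplicate_level = "run",
                        calibrators = list(generic_per_chip = 1,
                                           pooled_per_chip = 1),
                        expression_coupling = 0.5, seed = 110 + s)
    sim <- simulate_experiment(spec)
    shifts <- batch_shifts(sim$expression, sim$samples, "run")
    ft <- fidelity_table(shifts, magnitude_bins = c(0, 0.5))
    lo <- ft$r_pct[ft$threshold == 0]
    hi <- ft$r_pct[ft$threshold == 0.5]
    mean(hi - lo, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(gains > 0), 0.9)
})

test_that("calibrator comparison handles trivial and degenerate inputs", {
  a <- c(90, 92, 94, 96)
  same <- compare_calibrators(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p, 1)
  const <- compare_calibrators(a + 4, a)
  expect_true(const$degenerate)
  expect_true(is.na(const$p))
  expect_error(compare_calibrators(1, 2), "at least 2")
})

test_that("the paired t-test detects a consistent small improvement", {
  set.seed(113)
  hits <- vapply(1:100, function(i) {
    d <- rnorm(14, 0.04, 0.01)
    compare_calibrators(d, rep(0, 14))$p < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("batch-regulated probe counting respects strict boundaries", {
  delta <- matrix(0, 3, 14,
                  dimnames = list(c("pA", "pB", "pC"), NULL))
  delta[1, 1] <- 1.1    # > 2-fold in one pair
  delta[2, 1] <- 1.0    # exactly 2-fold: excluded (strict)
  delta[3, 1:5] <- 1.5  # 5 pairs only
  shifts <- structure(list(
    delta = delta,
    pairs = data.frame(pair_id = sprintf("d%02d", 1:14),
                       kind = "sample_duplicate", from = "R1", to = "R2",
                       sample_from = "x", sample_to = "y",
                       stringsAsFactors = FALSE)),
    class = "shift_collection")
  expect_setequal(count_batch_regulated(shifts, 2, min_pairs = 1),
                  c("pA", "pC"))
  expect_length(count_batch_regulated(shifts, 2, min_pairs = 6), 0)
  expect_error(count_batch_regulated(shifts, 1), "> 1")

  # monotone non-increasing in min_pairs and fold threshold
  set.seed(127)
  shifts$delta <- matrix(rnorm(3 * 14, 0, 1), 3, 14,
                         dimnames = dimnames(delta))
  n_by_pairs <- vapply(1:5, function(k)
    length(count_batch_regulated(shifts, 2, k)), integer(1))
  expect_true(all(diff(n_by_pairs) <= 0))
  n_by_fold <- vapply(c(1.5, 2, 3), function(f)
    length(count_batch_regulated(shifts, f, 1)), integer(1))
  expect_true(all(diff(n_by_fold) <= 0))
})
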