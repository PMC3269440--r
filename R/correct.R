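#' Fit the empirical-Bayes batch correction model
#'
#' Probe-wise location/scale batch adjustment in three stages. Stage 1
#' standardises the data: a per-probe location model (intercept, optional
#' covariates, and batch terms under the batch-size-weighted zero-sum
#' constraint) is fitted by least squares, a pooled per-probe SD is
#' computed, and the standardised residual grid z is formed. Stage 2
#' estimates, per batch and probe, the sample mean (additive effect, gamma)
#' and sample variance (multiplicative effect, delta^2) of z, then fits the
#' hyperpriors by the method of moments: a normal prior on gamma from the
#' cross-probe mean/variance of the gamma estimates, and an inverse-gamma
#' prior on delta^2 by matching its mean `theta/(lambda-1)` and variance
#' `theta^2/((lambda-1)^2 (lambda-2))` to the cross-probe moments. Stage 3
#' iterates the conditional posterior means of both parameters to
#' convergence; the final adjustments are the expected values of the
#' posterior distributions, which borrows strength across probes and gives
#' more stable estimates than the raw batch means and variances.
#'
#' With a single batch the adjustment is unidentifiable from the
#' standardisation and the model degenerates to the identity (zero additive,
#' unit scale).
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param batch_level name of the batch coordinate to correct for.
#' @param covariates optional character vector of sample-sheet columns
#'   (e.g. the biological group) retained in the location model so the
#'   biology is not removed with the batch effect.
#' @param shrink if `FALSE`, the raw per-batch estimates are used without
#'   empirical-Bayes shrinkage.
#' @param mean_only if `TRUE`, only additive effects are corrected
#'   (scale fixed at 1).
#' @param conv convergence threshold for the stage-3 iteration (max absolute
#'   parameter change).
#' @param max_iter stage-3 iteration cap.
#' @return An object of class `batch_correction_model`.
#' @export
combat_fit <- function(m, sheet, batch_level, covariates = NULL,
                       shrink = TRUE, mean_only = FALSE, conv = 1e-6,
                       max_iter = 100) {
  stopifnot(inherits(m, "expr_matrix"))
  check_samples(sheet, m)
  Y <- m$values
  N <- ncol(Y)
  idx <- match(colnames(Y), sheet$sample_id)
  batch <- factor(sheet[[batch_level]][idx])
  nb <- nlevels(batch)
  n_i <- as.vector(table(batch))
  if (any(n_i < 2L))
    stop("batch(es) with a single sample: ",
         paste(levels(batch)[n_i < 2L], collapse = ", "), call. = FALSE)

  batch_design <- matrix(0, N, nb,
                         dimnames = list(NULL, levels(batch)))
  batch_design[cbind(seq_len(N), as.integer(batch))] <- 1
  cov_design <- NULL
  if (!is.null(covariates)) {
    cdf <- as.data.frame(sheet)[idx, covariates, drop = FALSE]
    ## samples without a covariate value (e.g. control replicates have no
    ## biological group) form their own level rather than being dropped
    for (cc in covariates) {
      x <- as.character(cdf[[cc]])
      x[is.na(x)] <- ".none"
      cdf[[cc]] <- factor(x)
    }
    cov_design <- stats::model.matrix(
      stats::reformulate(covariates), data = cdf)[, -1L, drop = FALSE]
  }
  design <- cbind(batch_design, cov_design)
  if (qr(design)$rank < ncol(design))
    stop(paste("covariates are confounded with batch; correction would",
               "remove the biological signal"), call. = FALSE)

  ## stage 1: standardisation
  B_hat <- solve(crossprod(design), crossprod(design, t(Y)))
  grand_mean <- drop(crossprod(n_i / N, B_hat[seq_len(nb), , drop = FALSE]))
  stand_mean <- matrix(grand_mean, nrow(Y), N)
  if (!is.null(cov_design) && ncol(cov_design) > 0L)
    stand_mean <- stand_mean +
      t(cov_design %*% B_hat[-seq_len(nb), , drop = FALSE])
  var_pooled <- rowMeans((Y - t(design %*% B_hat))^2)
  if (any(var_pooled <= 0))
    stop("zero-variance probe(s); filter before correction: ",
         paste(utils::head(rownames(Y)[var_pooled <= 0], 5), collapse = ", "),
         call. = FALSE)
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  ## stage 2: per-batch per-probe moments + hyperpriors
  gamma_hat <- t(solve(crossprod(batch_design),
                       crossprod(batch_design, t(Z))))       # G x nb
  delta2_hat <- matrix(NA_real_, nrow(Y), nb)
  for (i in seq_len(nb))
    delta2_hat[, i] <- apply(Z[, batch == levels(batch)[i], drop = FALSE],
                             1L, stats::var)
  colnames(gamma_hat) <- colnames(delta2_hat) <- levels(batch)

  single_batch <- nb == 1L
  gamma_bar <- colMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 2L, stats::var)
  d_m <- colMeans(delta2_hat)
  d_s2 <- apply(delta2_hat, 2L, stats::var)
  if (!single_batch && shrink &&
      (any(!is.finite(tau2_bar)) || any(tau2_bar <= 0) ||
       any(!is.finite(d_s2)) || (!mean_only && any(d_s2 <= 0))))
    stop(paste("degenerate hyperparameters: cross-probe variance of the",
               "batch estimates is zero or non-finite"), call. = FALSE)
  ig <- ig_moment_match(d_m, d_s2)
  lambda <- ig$lambda
  theta <- ig$theta

  ## stage 3: posterior expectations
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  n_iter <- integer(nb)
  if (single_batch) {
    gamma_star[] <- 0
    delta2_star[] <- 1
  } else if (!shrink) {
    if (mean_only) delta2_star[] <- 1
  } else {
    for (i in seq_len(nb)) {
      Zb <- Z[, batch == levels(batch)[i], drop = FALSE]
      g_old <- gamma_hat[, i]
      d_old <- if (mean_only) rep(1, nrow(Y)) else delta2_hat[, i]
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (n_i[i] * tau2_bar[i] * gamma_hat[, i] +
                    d_old * gamma_bar[i]) /
          (n_i[i] * tau2_bar[i] + d_old)
        if (mean_only) {
          d_new <- d_old
        } else {
          sum2 <- rowSums((Zb - g_new)^2)
          d_new <- (theta[i] + 0.5 * sum2) / (n_i[i] / 2 + lambda[i] - 1)
        }
        delta <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new
        d_old <- d_new
        if (delta < conv || it >= max_iter) break
      }
      gamma_star[, i] <- g_old
      delta2_star[, i] <- d_old
      n_iter[i] <- it
    }
    if (mean_only) delta2_star[] <- 1
  }

  structure(list(batch_level = batch_level, covariates = covariates,
                 sample_batch = stats::setNames(as.character(batch),
                                                colnames(Y)),
                 batches = levels(batch), n_i = stats::setNames(n_i,
                                                                levels(batch)),
                 B_hat = B_hat, grand_mean = grand_mean,
                 stand_mean = stand_mean, var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_bar = gamma_bar, tau2_bar = tau2_bar,
                 lambda = lambda, theta = theta,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 shrink = shrink, mean_only = mean_only, n_iter = n_iter,
                 probe_ids = rownames(Y)),
            class = "batch_correction_model")
}

## Inverse-gamma hyperprior by the method of moments: matches the prior
## mean theta/(lambda-1) and variance theta^2/((lambda-1)^2 (lambda-2)) to
## the observed cross-probe mean and variance of the scale estimates.
ig_moment_match <- function(m, s2) {
  list(lambda = (m^2 + 2 * s2) / s2,
       theta = (m^3 + m * s2) / s2)
}

#' Apply a fitted batch correction
#'
#' Adjusted value for probe g on sample j in batch i:
#' `sigma_g / delta*_ig * (z_gj - gamma*_ig) + alpha_g + covariate fit`.
#' Probe and sample order are never altered.
#'
#' @param m an `expr_matrix` whose samples were part of the model fit.
#' @param model a `batch_correction_model` from [combat_fit()].
#' @return The corrected `expr_matrix` (detection carried through).
#' @export
combat_apply <- function(m, model) {
  stopifnot(inherits(m, "expr_matrix"),
            inherits(model, "batch_correction_model"))
  ids <- colnames(m$values)
  unknown <- setdiff(ids, names(model$sample_batch))
  if (length(unknown))
    stop("sample(s) with unknown batch: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  if (!identical(rownames(m$values), model$probe_ids))
    stop("probe set differs from the fitted model", call. = FALSE)
  j <- match(ids, names(model$sample_batch))
  batch <- model$sample_batch[j]
  bi <- match(batch, model$batches)
  Z <- (m$values - model$stand_mean[, j, drop = FALSE]) /
    sqrt(model$var_pooled)
  adj <- (Z - model$gamma_star[, bi, drop = FALSE]) /
    sqrt(model$delta2_star[, bi, drop = FALSE])
  out <- adj * sqrt(model$var_pooled) + model$stand_mean[, j, drop = FALSE]
  dimnames(out) <- dimnames(m$values)
  expression_matrix(out, m$detection)
}

#' Fit and apply batch correction, optionally at several nested levels
#'
#' Sequential correction outermost level first (e.g. by experiment, then by
#' run), each stage refitting on the output of the previous one.
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet`.
#' @param batch_levels character vector of batch coordinates, outermost
#'   first.
#' @param ... passed on to [combat_fit()].
#' @return The corrected `expr_matrix`.
#' @export
combat_correct <- function(m, sheet, batch_levels, ...) {
  for (lv in batch_levels)
    m <- combat_apply(m, combat_fit(m, sheet, lv, ...))
  m
}

#' Mean-centring batch correction
#'
#' Per probe and batch, subtracts the batch mean and restores the grand
#' mean. Baseline alternative to the empirical-Bayes correction; equals it
#' in the limit of no scale adjustment and no shrinkage on balanced designs.
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param batch_level batch coordinate to centre on.
#' @return The corrected `expr_matrix`.
#' @export
mean_center <- function(m, sheet, batch_level) {
  stopifnot(inherits(m, "expr_matrix"))
  check_samples(sheet, m)
  Y <- m$values
  batch <- factor(sheet[[batch_level]][match(colnames(Y), sheet$sample_id)])
  grand <- rowMeans(Y)
  out <- Y
  for (b in levels(batch)) {
    cols <- batch == b
    out[, cols] <- Y[, cols, drop = FALSE] -
      rowMeans(Y[, cols, drop = FALSE]) + grand
  }
  expression_matrix(out, m$detection)
}
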