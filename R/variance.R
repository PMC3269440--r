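#' Specify a nested variance model
#'
#' The model has an optional fixed biological factor (e.g. cell line or
#' treatment group) and an ordered list of strictly nested random batch
#' levels from outermost to innermost; the residual stratum (variation
#' between arrays within the innermost listed level) is implied.
#'
#' @param random_levels character vector of batch coordinate names,
#'   outermost first; may be empty (residual only).
#' @param fixed_factor optional name of the sample-sheet column holding the
#'   fixed biological variable.
#' @return A list of class `nested_model_spec`.
#' @export
nested_model_spec <- function(random_levels, fixed_factor = NULL) {
  stopifnot(is.character(random_levels))
  if (!is.null(fixed_factor) && fixed_factor %in% random_levels)
    stop("fixed_factor must not be among the random levels", call. = FALSE)
  structure(list(random_levels = random_levels, fixed_factor = fixed_factor),
            class = "nested_model_spec")
}

## Design structure shared by every probe: unit factors, indicator
## cross-products and fixed-effect design, computed once per sample sheet.
build_nested_design <- function(sheet, spec, sample_ids) {
  sub <- as.data.frame(sheet)[match(sample_ids, sheet$sample_id), ,
                              drop = FALSE]
  lv <- spec$random_levels
  for (l in lv)
    if (!l %in% colnames(sub))
      stop("sample sheet lacks batch level '", l, "'", call. = FALSE)
  check_nesting(sub, lv)
  n <- nrow(sub)
  factors <- list()
  estimable <- character(0)
  for (i in seq_along(lv)) {
    f <- factor(do.call(paste, c(sub[lv[seq_len(i)]], sep = "\r")))
    factors[[lv[i]]] <- f
    if (nlevels(f) >= 2L) estimable <- c(estimable, lv[i])
  }
  X <- if (is.null(spec$fixed_factor)) matrix(1, n, 1L) else {
    ff <- factor(sub[[spec$fixed_factor]])
    if (anyNA(ff))
      stop("fixed factor has missing values for some samples", call. = FALSE)
    stats::model.matrix(~ff)
  }
  K <- lapply(factors[estimable], function(f) {
    Z <- stats::model.matrix(~ 0 + f)
    tcrossprod(Z)
  })
  list(sub = sub, levels = lv, estimable = estimable, factors = factors,
       K = K, X = X, n = n)
}

## Balanced-design check: equal children counts at every nesting step and,
## if a fixed factor is present, equal counts of its levels within every
## innermost unit.
is_balanced_design <- function(design) {
  lv <- design$levels
  sub <- design$sub
  prev <- factor(rep(1L, design$n))
  for (l in lv) {
    f <- design$factors[[l]]
    kids <- tapply(as.integer(f), prev, function(x) length(unique(x)))
    if (length(unique(kids)) != 1L) return(FALSE)
    prev <- f
  }
  counts <- table(prev)
  if (length(unique(counts)) != 1L) return(FALSE)
  if (ncol(design$X) > 1L) {
    inner <- if (length(lv)) design$factors[[lv[length(lv)]]] else
      factor(rep(1L, design$n))
    ff <- design$fixed_values
    tab <- table(inner, ff)
    if (length(unique(as.vector(tab))) != 1L) return(FALSE)
  }
  TRUE
}

#' Nested variance components by expected mean squares
#'
#' Classical balanced nested ANOVA: mean squares are computed at every
#' nesting stratum and the triangular expected-mean-squares system is solved
#' for the variance components; negative solutions are truncated to zero.
#' Requires a balanced design (equal children counts at every level); on
#' unbalanced data an error directs the caller to [fit_nested_reml()].
#'
#' @param y numeric vector of one probe's log2 values, named by sample id or
#'   aligned with `sheet` rows.
#' @param sheet a `sample_sheet`.
#' @param spec a [nested_model_spec()].
#' @return List with `sd` (named SDs: each random level, then `residual`),
#'   `variance` (the components), and `df` per stratum.
#' @export
fit_nested_mom <- function(y, sheet, spec) {
  ids <- if (!is.null(names(y))) names(y) else sheet$sample_id
  Y <- matrix(y, 1L, dimnames = list("probe", ids))
  fit <- fit_nested_mom_matrix(Y, sheet, spec)
  list(sd = fit$sd[1L, ], variance = fit$variance[1L, ], df = fit$df)
}

## Vectorised EMS solver over a probes x samples matrix.
fit_nested_mom_matrix <- function(Y, sheet, spec, design = NULL) {
  if (is.null(design)) design <- build_nested_design(sheet, spec, colnames(Y))
  design$fixed_values <- if (!is.null(spec$fixed_factor))
    design$sub[[spec$fixed_factor]]
  if (!is_balanced_design(design))
    stop("design is unbalanced; use fit_nested_reml()", call. = FALSE)
  lv <- design$levels
  if (!setequal(design$estimable, lv))
    stop("level(s) with a single unit cannot be estimated by EMS: ",
         paste(setdiff(lv, design$estimable), collapse = ", "), call. = FALSE)
  n <- design$n
  G <- nrow(Y)
  df_fixed <- ncol(design$X) - 1L
  if (df_fixed > 0L) {
    ff <- factor(design$fixed_values)
    gm <- t(rowsum(t(Y), as.integer(ff)) / as.vector(table(ff)))
    Y <- Y - gm[, as.integer(ff), drop = FALSE]
  }
  ## unit means outermost -> innermost; stratum sums of squares
  grand <- rowMeans(Y)
  prev_mean <- matrix(grand, G, n)
  prev_units <- 1L
  ss <- matrix(NA_real_, G, length(lv) + 1L,
               dimnames = list(rownames(Y), c(lv, "residual")))
  df <- numeric(length(lv) + 1L)
  m_per <- numeric(length(lv))  # observations per unit at each level
  for (i in seq_along(lv)) {
    f <- design$factors[[lv[i]]]
    counts <- as.vector(table(f))
    mu <- t(rowsum(t(Y), as.integer(f)) / counts)  # G x units
    mu_exp <- mu[, as.integer(f), drop = FALSE]
    ss[, i] <- rowSums((mu_exp - prev_mean)^2)
    df[i] <- nlevels(f) - prev_units
    m_per[i] <- counts[1L]
    prev_mean <- mu_exp
    prev_units <- nlevels(f)
  }
  ss[, length(lv) + 1L] <- rowSums((Y - prev_mean)^2)
  df[length(lv) + 1L] <- n - prev_units - df_fixed
  if (df[length(lv) + 1L] <= 0L)
    stop("no residual degrees of freedom in this design", call. = FALSE)
  ms <- sweep(ss, 2L, df, "/")
  vc <- matrix(NA_real_, G, length(lv) + 1L,
               dimnames = dimnames(ss))
  vc[, length(lv) + 1L] <- ms[, length(lv) + 1L]
  for (i in rev(seq_along(lv)))
    vc[, i] <- (ms[, i] - ms[, i + 1L]) / m_per[i]
  raw <- vc
  vc[vc < 0] <- 0
  list(sd = sqrt(vc), variance = vc, variance_raw = raw,
       df = stats::setNames(df, colnames(ss)))
}

#' Nested variance components by restricted maximum likelihood
#'
#' Maximises the restricted log-likelihood of the Gaussian nested model
#' (fixed factor by generalised least squares, nonnegative variance
#' components) over log-variances with analytic gradients; components are
#' kept nonnegative by a box bound that projects vanishing components onto
#' the zero boundary. On balanced designs with interior solutions the
#' estimates agree with the expected-mean-squares solution.
#'
#' Random levels represented by a single unit are inestimable and reported
#' as `NA`.
#'
#' @param y numeric vector of one probe's values, named by sample id or
#'   aligned with `sheet` rows.
#' @param sheet a `sample_sheet`.
#' @param spec a [nested_model_spec()].
#' @param tol convergence tolerance on the restricted log-likelihood change.
#' @param max_iter iteration cap for the optimiser.
#' @param design precomputed design structure (internal use).
#' @return List with `sd`, `variance` (named, `NA` for inestimable levels),
#'   `fixed_effects` (GLS estimates at the optimum), `converged`, and
#'   `loglik` (restricted log-likelihood).
#' @export
fit_nested_reml <- function(y, sheet, spec, tol = 1e-8, max_iter = 200,
                            design = NULL) {
  if (is.null(design)) {
    ids <- if (!is.null(names(y))) names(y) else sheet$sample_id
    design <- build_nested_design(sheet, spec, ids)
  }
  y <- as.numeric(y)
  n <- design$n
  X <- design$X
  p <- ncol(X)
  K <- design$K
  k <- length(K)
  lv <- design$levels

  tot <- stats::var(y)
  out_names <- c(lv, "residual")
  if (!is.finite(tot) || tot <= 0) {
    vc <- stats::setNames(rep(0, length(lv) + 1L), out_names)
    vc[setdiff(lv, design$estimable)] <- NA_real_
    return(list(sd = sqrt(vc), variance = vc,
                fixed_effects = c(mean(y), rep(0, p - 1L)),
                converged = TRUE, loglik = NA_real_,
                flag = "zero_variance"))
  }

  lb <- log(tot) - 32          # boundary: component numerically zero
  ub <- log(tot) + 6

  neg_reml <- function(theta) {
    s2 <- exp(theta)
    V <- diag(s2[k + 1L], n)
    for (i in seq_len(k)) V <- V + s2[i] * K[[i]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(value = 1e10, grad = rep(0, k + 1L)))
    A <- backsolve(R, X, transpose = TRUE)
    b <- backsolve(R, y, transpose = TRUE)
    XtViX <- crossprod(A)
    XtViy <- crossprod(A, b)
    cX <- chol(XtViX)
    beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
    quad <- sum(b^2) - sum(XtViy * beta)
    val <- 0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))) + quad)
    ## gradient via P = Vi - Vi X (X'ViX)^-1 X'Vi
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% backsolve(cX, backsolve(cX, t(ViX), transpose = TRUE))
    Py <- drop(P %*% y)
    g <- numeric(k + 1L)
    for (i in seq_len(k)) {
      f <- design$factors[[design$estimable[i]]]
      agg_P <- rowsum(Py, f)
      trPK <- sum(P * K[[i]])
      g[i] <- 0.5 * (trPK - sum(agg_P^2)) * s2[i]
    }
    g[k + 1L] <- 0.5 * (sum(diag(P)) - sum(Py^2)) * s2[k + 1L]
    list(value = val, grad = g, beta = beta)
  }

  ## start from EMS when balanced, else equal split
  start <- rep(tot / (k + 1L), k + 1L)
  design$fixed_values <- if (!is.null(spec$fixed_factor))
    design$sub[[spec$fixed_factor]]
  if (is_balanced_design(design) && setequal(design$estimable, lv)) {
    mom <- tryCatch(
      fit_nested_mom_matrix(matrix(y, 1L, dimnames = list("p", NULL)),
                            sheet, spec, design = design),
      error = function(e) NULL)
    if (!is.null(mom)) start <- pmax(mom$variance[1L, ], tot * 1e-3)
  } else start <- pmax(start, tot * 1e-3)
  theta0 <- pmin(pmax(log(start), lb + 1), ub)

  opt <- stats::optim(theta0,
                      fn = function(th) neg_reml(th)$value,
                      gr = function(th) neg_reml(th)$grad,
                      method = "L-BFGS-B", lower = lb, upper = ub,
                      control = list(maxit = max_iter,
                                     factr = tol / .Machine$double.eps,
                                     pgtol = 1e-8))
  ## boundary polish: the restricted likelihood is flat in log-variance as a
  ## component vanishes, so the optimiser can stall short of the bound;
  ## snap any component to zero when doing so costs less than `tol`.
  par <- opt$par
  f_cur <- neg_reml(par)$value
  for (i in order(exp(par))) {
    if (exp(par[i]) >= tot * 1e-3 || par[i] <= lb) next
    cand <- par
    cand[i] <- lb
    f_cand <- neg_reml(cand)$value
    if (f_cand <= f_cur + tol * max(1, abs(f_cur))) {
      par <- cand
      f_cur <- f_cand
    }
  }
  opt$par <- par
  final <- neg_reml(opt$par)
  s2 <- exp(opt$par)
  s2[s2 < tot * 1e-10] <- 0
  vc <- stats::setNames(rep(NA_real_, length(lv) + 1L), out_names)
  vc[design$estimable] <- s2[seq_len(k)]
  vc["residual"] <- s2[k + 1L]
  list(sd = sqrt(vc), variance = vc,
       fixed_effects = drop(final$beta),
       converged = opt$convergence == 0L,
       loglik = -final$value, flag = if (opt$convergence == 0L) "ok"
       else "non_convergence")
}

#' Probe-wise nested variance decomposition
#'
#' Applies the nested variance model to every probe of an expression matrix
#' and summarises the per-level standard deviations across probes. Percent
#' contributions are computed on the SD scale: the percent attributed to
#' level l is `100 * meanSD_l / sum_k meanSD_k`, where the mean is taken
#' over all successfully fitted probes.
#'
#' @param m an `expr_matrix` (typically detection-filtered and normalised).
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param spec a [nested_model_spec()].
#' @param method `"reml"` (default) or `"mom"` (balanced designs only;
#'   considerably faster since it is vectorised across probes).
#' @param subset_samples optional sample ids to restrict the fit to (for
#'   example only the generic control replicates).
#' @return An object of class `variance_decomposition` with elements
#'   `per_probe` (data.frame of per-probe SDs, convergence flags), `summary`
#'   (mean SD and percent contribution per level), `fixed_effects` and
#'   `method`. Per-probe failures are flagged, never fatal.
#' @export
decompose_variance <- function(m, sheet, spec,
                               method = c("reml", "mom"),
                               subset_samples = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_matrix"), inherits(spec, "nested_model_spec"))
  check_samples(sheet, m)
  Y <- m$values
  if (!is.null(subset_samples)) Y <- Y[, subset_samples, drop = FALSE]
  design <- build_nested_design(sheet, spec, colnames(Y))
  lv <- spec$random_levels
  comp_names <- c(lv, "residual")

  if (length(lv) == 0L) {
    ## residual-only model: per-probe SD about the fixed-effect fit
    X <- design$X
    H <- X %*% solve(crossprod(X), t(X))
    res <- Y - Y %*% t(H)
    dfres <- ncol(Y) - ncol(X)
    sds <- sqrt(rowSums(res^2) / dfres)
    per_probe <- data.frame(probe_id = rownames(Y), residual = sds,
                            converged = TRUE, flag = "ok",
                            stringsAsFactors = FALSE)
    summ <- data.frame(level = "residual", mean_sd = mean(sds),
                       rms_sd = sqrt(mean(sds^2)),
                       pct_contribution = 100, stringsAsFactors = FALSE)
    return(structure(list(per_probe = per_probe, summary = summ,
                          fixed_effects = NULL, method = method,
                          levels = comp_names),
                     class = "variance_decomposition"))
  }

  G <- nrow(Y)
  if (method == "mom") {
    fit <- fit_nested_mom_matrix(Y, sheet, spec, design = design)
    sd_mat <- fit$sd
    converged <- rep(TRUE, G)
    flags <- rep("ok", G)
    fixed <- NULL
  } else {
    sd_mat <- matrix(NA_real_, G, length(comp_names),
                     dimnames = list(rownames(Y), comp_names))
    converged <- logical(G)
    flags <- character(G)
    fixed <- matrix(NA_real_, G, ncol(design$X))
    for (g in seq_len(G)) {
      fit <- tryCatch(
        fit_nested_reml(Y[g, ], sheet, spec, design = design),
        error = function(e) NULL)
      if (is.null(fit)) {
        flags[g] <- "fit_error"
        converged[g] <- FALSE
        next
      }
      sd_mat[g, ] <- fit$sd[comp_names]
      converged[g] <- fit$converged
      flags[g] <- fit$flag
      fixed[g, ] <- fit$fixed_effects
    }
  }

  ok <- converged & flags == "ok"
  mean_sd <- colMeans(sd_mat[ok, , drop = FALSE], na.rm = TRUE)
  rms_sd <- sqrt(colMeans(sd_mat[ok, , drop = FALSE]^2, na.rm = TRUE))
  est <- !is.na(mean_sd)
  pct <- rep(NA_real_, length(mean_sd))
  pct[est] <- 100 * mean_sd[est] / sum(mean_sd[est])
  per_probe <- data.frame(probe_id = rownames(Y), sd_mat,
                          converged = converged, flag = flags,
                          stringsAsFactors = FALSE, check.names = FALSE)
  summ <- data.frame(level = comp_names, mean_sd = unname(mean_sd),
                     rms_sd = unname(rms_sd),
                     pct_contribution = unname(pct),
                     stringsAsFactors = FALSE)
  structure(list(per_probe = per_probe, summary = summ,
                 fixed_effects = fixed, method = method,
                 levels = comp_names, n_probes_used = sum(ok)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance_decomposition (%s) over %d probes\n", x$method,
              nrow(x$per_probe)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
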