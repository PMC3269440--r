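#' Specify a synthetic nested microarray experiment
#'
#' The generator emulates the hierarchical noise structure of a BeadChip
#' style experiment: arrays sit on chips, chips in runs, runs in experiments
#' (one sample per array, the array being the residual-bearing unit). Each
#' batch unit at each level draws, per probe, an additive Gaussian effect on
#' the log2 scale; a probe's realised shift in a given sample is further
#' modulated by a GC-vulnerability multiplier and an expression-coupling
#' weight.
#'
#' The observed value for probe g on array j is
#' \deqn{y_{gj} = \mu_g + \beta_{g,grp(j)} + \sum_l b_{u_l(j),g}\, v_l(g)\, w_{gj} + \varepsilon_{gj}}
#' with \eqn{b \sim N(0, \sigma_l^2)}, \eqn{\varepsilon \sim N(0,
#' \sigma_e^2)}, \eqn{v_l(g)} the vulnerability multiplier (step function of
#' GC fraction) and \eqn{w_{gj} = (1-\kappa) + \kappa\, s_{gj}} where
#' \eqn{s_{gj}} is the within-sample rank of the probe's true expression
#' mapped to \[0, 1\]. With `expression_coupling = 0` and multiplier 1 the
#' model is exactly the balanced nested Gaussian model assumed by the
#' variance module.
#'
#' @param n_probes number of probes.
#' @param nesting named integer vector of children-per-parent counts,
#'   outermost level first and ending with arrays per innermost batch unit,
#'   e.g. `c(experiment = 3, run = 2, chip = 2, array = 2)`. All names but
#'   the last are batch coordinate levels.
#' @param level_sd named numeric vector of per-level random-effect SDs
#'   (log2 scale), one per batch level.
#' @param residual_sd residual (within innermost unit) SD, log2 scale.
#' @param baseline list with `mean` and `sd` of the per-probe baseline log2
#'   expression.
#' @param group_design `NULL` for no biological groups, else a list with
#'   `groups` (labels), `frac_differential` (fraction of probes truly
#'   differential) and `effect_sd` (SD of the log2 effect for non-reference
#'   groups at differential probes).
#' @param duplicate_plan number of biological source samples hybridised
#'   twice, in two distinct units of `duplicate_level`.
#' @param duplicate_level batch level across which duplicates are split.
#' @param calibrators list with `generic_per_chip` and `pooled_per_chip`
#'   replicate counts per innermost batch unit. The generic control has a
#'   fixed expression profile independent of the biological samples; the
#'   pooled control profile is the log2-scale mean of all biological source
#'   profiles.
#' @param gc_model list with `cutoff` (GC fraction below which probes are
#'   vulnerable), `multiplier` (factor applied to the level SDs of
#'   vulnerable probes) and `levels` (batch levels affected; `NULL` = all).
#' @param expression_coupling kappa in \[0, 1\]: strength with which a
#'   probe's realised batch shift in a sample depends on that sample's true
#'   expression of the probe.
#' @param detection_model list with `midpoint`, `scale`, `noise_sd` of the
#'   logistic map from true log2 expression to detection confidence.
#' @param outlier_chip optional list `(chip = label or index, multiplier)`
#'   inflating one innermost batch unit's SD.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `design_spec`.
#' @export
design_spec <- function(n_probes = 500,
                        nesting = c(experiment = 3, run = 2, chip = 2,
                                    array = 4),
                        level_sd = c(experiment = 0.30, run = 0.15,
                                     chip = 0.10),
                        residual_sd = 0.20,
                        baseline = list(mean = 7, sd = 2),
                        group_design = list(groups = c("pre", "post"),
                                            frac_differential = 0.1,
                                            effect_sd = 1),
                        duplicate_plan = 4,
                        duplicate_level = "run",
                        calibrators = list(generic_per_chip = 1,
                                           pooled_per_chip = 1),
                        gc_model = list(cutoff = 0.55, multiplier = 1,
                                        levels = NULL),
                        expression_coupling = 0.5,
                        detection_model = list(midpoint = 4, scale = 0.7,
                                               noise_sd = 0.5),
                        outlier_chip = NULL,
                        seed = 1) {
  spec <- list(n_probes = n_probes, nesting = nesting, level_sd = level_sd,
               residual_sd = residual_sd, baseline = baseline,
               group_design = group_design, duplicate_plan = duplicate_plan,
               duplicate_level = duplicate_level, calibrators = calibrators,
               gc_model = gc_model,
               expression_coupling = expression_coupling,
               detection_model = detection_model,
               outlier_chip = outlier_chip, seed = seed)
  validate_design_spec(spec)
  structure(spec, class = "design_spec")
}

validate_design_spec <- function(spec) {
  stopifnot(spec$n_probes >= 1, length(spec$nesting) >= 2)
  if (is.null(names(spec$nesting)) || any(!nzchar(names(spec$nesting))))
    stop("`nesting` must be a named vector", call. = FALSE)
  if (any(spec$nesting < 1))
    stop("nesting children counts must be >= 1", call. = FALSE)
  lv <- utils::head(names(spec$nesting), -1L)
  if (!setequal(names(spec$level_sd), lv))
    stop("`level_sd` must name exactly the batch levels: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (any(spec$level_sd < 0) || spec$residual_sd < 0)
    stop("all SDs must be >= 0", call. = FALSE)
  k <- spec$expression_coupling
  if (k < 0 || k > 1)
    stop("expression_coupling must lie in [0, 1]", call. = FALSE)
  if (!is.null(spec$group_design)) {
    fd <- spec$group_design$frac_differential
    if (fd < 0 || fd > 1)
      stop("frac_differential must lie in [0, 1]", call. = FALSE)
  }
  if (spec$duplicate_plan > 0 &&
      !spec$duplicate_level %in% lv)
    stop("duplicate_level must be one of the batch levels", call. = FALSE)
  invisible(spec)
}

batch_level_names <- function(spec) utils::head(names(spec$nesting), -1L)

## Fully-qualified nested unit labels, e.g. experiment "E1", run "E1.R1".
build_array_frame <- function(spec) {
  lv <- batch_level_names(spec)
  counts <- spec$nesting
  grids <- lapply(rev(seq_along(counts)), function(i)
    seq_len(counts[i]))
  g <- do.call(expand.grid, grids)  # innermost varies fastest
  g <- g[, rev(seq_along(counts)), drop = FALSE]
  colnames(g) <- names(counts)
  g <- g[do.call(order, g), , drop = FALSE]
  out <- list()
  for (i in seq_along(lv)) {
    prefix <- toupper(substr(lv[i], 1, 1))
    lab <- paste0(prefix, g[[i]])
    if (i > 1L) lab <- paste(out[[lv[i - 1L]]], lab, sep = ".")
    out[[lv[i]]] <- lab
  }
  out$sample_id <- sprintf("s%03d", seq_len(nrow(g)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

## Assign roles, duplicate ids, source samples and groups to arrays.
allocate_samples <- function(spec) {
  arrays <- build_array_frame(spec)
  lv <- batch_level_names(spec)
  chip_lv <- lv[length(lv)]
  arrays$role <- "biological"
  arrays$duplicate_id <- NA_character_
  arrays$source_id <- NA_character_

  cal <- spec$calibrators
  n_gen <- if (is.null(cal$generic_per_chip)) 0L else cal$generic_per_chip
  n_pool <- if (is.null(cal$pooled_per_chip)) 0L else cal$pooled_per_chip
  for (chip in unique(arrays[[chip_lv]])) {
    idx <- which(arrays[[chip_lv]] == chip)
    need <- n_gen + n_pool
    if (need > length(idx))
      stop("calibrator counts exceed arrays per chip", call. = FALSE)
    if (n_gen > 0) {
      gi <- idx[seq_len(n_gen)]
      arrays$role[gi] <- "generic_control"
      arrays$duplicate_id[gi] <- "generic"
      arrays$source_id[gi] <- "generic"
    }
    if (n_pool > 0) {
      pi <- idx[n_gen + seq_len(n_pool)]
      arrays$role[pi] <- "pooled_control"
      arrays$duplicate_id[pi] <- "pool"
      arrays$source_id[pi] <- "pool"
    }
  }

  ## duplicates: split each duplicated source across two distinct units of
  ## duplicate_level, cycling over consecutive unit pairs
  n_dup <- spec$duplicate_plan
  if (n_dup > 0) {
    units <- unique(arrays[[spec$duplicate_level]])
    if (length(units) < 2L)
      stop("duplicate_plan requires >= 2 units at level '",
           spec$duplicate_level, "'", call. = FALSE)
    pairs <- utils::combn(units, 2L)
    free <- function(u) which(arrays[[spec$duplicate_level]] == u &
                                arrays$role == "biological" &
                                is.na(arrays$source_id))
    for (d in seq_len(n_dup)) {
      placed <- FALSE
      for (p in seq_len(ncol(pairs))) {
        pp <- (p + d - 2L) %% ncol(pairs) + 1L
        f1 <- free(pairs[1L, pp]); f2 <- free(pairs[2L, pp])
        if (length(f1) && length(f2)) {
          id <- sprintf("dup%02d", d)
          arrays$duplicate_id[c(f1[1L], f2[1L])] <- id
          arrays$source_id[c(f1[1L], f2[1L])] <- id
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("duplicate_plan exceeds available cross-batch array pairs",
             call. = FALSE)
    }
  }

  single <- which(arrays$role == "biological" & is.na(arrays$source_id))
  arrays$source_id[single] <- sprintf("src%03d", seq_along(single))

  ## biological groups, round-robin over sources in array order so groups
  ## stay blocked (not confounded) across chips
  arrays$group <- NA_character_
  gd <- spec$group_design
  if (!is.null(gd)) {
    sources <- unique(arrays$source_id[arrays$role == "biological"])
    grp <- gd$groups[(seq_along(sources) - 1L) %% length(gd$groups) + 1L]
    names(grp) <- sources
    bio <- arrays$role == "biological"
    arrays$group[bio] <- grp[arrays$source_id[bio]]
  }
  arrays
}

#' Simulate a nested microarray experiment
#'
#' Generates an expression matrix, sample sheet, probe sheet and the full
#' simulation truth (realised effects) for a [design_spec()]. When `truth`
#' from a previous run is supplied, the probe-level quantities (baselines,
#' group effects, GC fractions, control profiles) are reused and only the
#' batch/residual draws are fresh, which simulates a replicate experiment of
#' the same biological study.
#'
#' @param spec a [design_spec()].
#' @param truth optional `simulation_truth` from a previous call with a
#'   compatible spec.
#' @return A list with elements `expression` (an [expression_matrix()] with
#'   detection confidences), `samples` (a [sample_sheet()]), `probes` (a
#'   [probe_sheet()]) and `truth` (class `simulation_truth`).
#' @export
simulate_experiment <- function(spec, truth = NULL) {
  validate_design_spec(spec)
  set.seed(spec$seed)
  G <- spec$n_probes
  lv <- batch_level_names(spec)

  if (is.null(truth)) {
    probe_id <- sprintf("p%05d", seq_len(G))
    gc_target <- stats::rbeta(G, 6, 4)
    sequences <- vapply(gc_target, random_probe_sequence, character(1L))
    gc <- gc_fraction(sequences)
    probes <- probe_sheet(data.frame(
      probe_id = probe_id, sequence = sequences,
      gene_id = sprintf("g%05d", seq_len(G)),
      strand = sample(c("+", "-"), G, replace = TRUE),
      probe_position_fraction = stats::runif(G),
      n_transcripts = 1L + stats::rpois(G, 1),
      n_exons = 1L + stats::rpois(G, 8),
      stringsAsFactors = FALSE))
    baseline <- stats::rnorm(G, spec$baseline$mean, spec$baseline$sd)
    gd <- spec$group_design
    groups <- if (is.null(gd)) character(0) else gd$groups
    effects <- matrix(0, G, length(groups),
                      dimnames = list(probe_id, groups))
    if (length(groups) > 1L) {
      is_diff <- stats::runif(G) < gd$frac_differential
      for (k in seq_along(groups)[-1L])
        effects[is_diff, k] <- stats::rnorm(sum(is_diff), 0, gd$effect_sd)
    }
    generic_profile <- stats::rnorm(G, spec$baseline$mean, spec$baseline$sd)
  } else {
    probes <- truth$probes
    probe_id <- probes$probe_id
    gc <- probes$gc_fraction
    baseline <- truth$baseline
    effects <- truth$group_effects
    generic_profile <- truth$generic_profile
    if (length(baseline) != G)
      stop("supplied truth does not match n_probes", call. = FALSE)
  }

  arrays <- allocate_samples(spec)
  N <- nrow(arrays)

  ## true profiles per source
  bio_sources <- unique(arrays$source_id[arrays$role == "biological"])
  src_profile <- matrix(baseline, G, length(bio_sources),
                        dimnames = list(probe_id, bio_sources))
  if (ncol(effects) > 0) {
    src_group <- arrays$group[match(bio_sources, arrays$source_id)]
    for (s in seq_along(bio_sources))
      if (!is.na(src_group[s]))
        src_profile[, s] <- src_profile[, s] + effects[, src_group[s]]
  }
  pool_profile <- rowMeans(src_profile)

  profile <- matrix(NA_real_, G, N,
                    dimnames = list(probe_id, arrays$sample_id))
  for (j in seq_len(N)) {
    profile[, j] <- switch(arrays$role[j],
                           biological = src_profile[, arrays$source_id[j]],
                           generic_control = generic_profile,
                           pooled_control = pool_profile)
  }

  ## expression-coupling weight: rank-based monotone map to [0, 1]
  kappa <- spec$expression_coupling
  w <- if (kappa > 0) {
    u <- apply(profile, 2L, function(x) (rank(x) - 0.5) / G)
    (1 - kappa) + kappa * u
  } else matrix(1, G, N)

  ## GC vulnerability multiplier per probe and level
  gm <- spec$gc_model
  vuln <- if (is.null(gm)) rep(1, G) else
    ifelse(gc < gm$cutoff, gm$multiplier, 1)
  gc_levels <- if (is.null(gm) || is.null(gm$levels)) lv else gm$levels

  ## nested random effects and composed shifts
  random_effects <- list()
  shift <- matrix(0, G, N, dimnames = dimnames(profile))
  chip_lv <- lv[length(lv)]
  for (l in lv) {
    units <- unique(arrays[[l]])
    b <- matrix(stats::rnorm(G * length(units), 0, spec$level_sd[[l]]),
                G, length(units), dimnames = list(probe_id, units))
    oc <- spec$outlier_chip
    if (!is.null(oc) && l == chip_lv) {
      tgt <- if (is.character(oc$chip)) oc$chip else units[oc$chip]
      b[, tgt] <- b[, tgt] * oc$multiplier
    }
    random_effects[[l]] <- b
    v_l <- if (l %in% gc_levels) vuln else rep(1, G)
    shift <- shift + (b[, arrays[[l]], drop = FALSE] * v_l) * w
  }
  eps <- matrix(stats::rnorm(G * N, 0, spec$residual_sd), G, N)
  values <- profile + shift + eps

  dm <- spec$detection_model
  detection <- stats::plogis(
    (profile + matrix(stats::rnorm(G * N, 0, dm$noise_sd), G, N) -
       dm$midpoint) / dm$scale)
  dimnames(detection) <- dimnames(values)

  sheet <- sample_sheet(arrays[, c("sample_id", "role", "group",
                                   "duplicate_id", "source_id", lv)],
                        batch_levels = lv)
  truth_out <- structure(list(
    probes = probes, baseline = stats::setNames(baseline, probe_id),
    group_effects = effects, generic_profile = generic_profile,
    pool_profile = pool_profile, source_profiles = src_profile,
    profile = profile, random_effects = random_effects,
    batch_shift = shift, weights = w, vulnerability = vuln,
    roles = stats::setNames(arrays$role, arrays$sample_id),
    gc_fraction = stats::setNames(gc, probe_id), spec = spec),
    class = "simulation_truth")

  list(expression = expression_matrix(values, detection),
       samples = sheet, probes = probes, truth = truth_out)
}

random_probe_sequence <- function(gc_target, length = 50L) {
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' True profile of a pooled control
#'
#' The pooled calibrator's expression profile is the per-probe arithmetic
#' mean, on the log2 scale, of the member samples' true profiles (a
#' well-mixed approximation to physically pooling the RNA).
#'
#' @param truth a `simulation_truth`.
#' @param member_samples character vector of biological sample ids (or
#'   source ids) entering the pool.
#' @return Named numeric vector: the pool's true log2 profile per probe.
#' @export
make_pooled_control <- function(truth, member_samples) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (length(member_samples) == 0L)
    stop("empty member list", call. = FALSE)
  ids <- member_samples
  srcs <- colnames(truth$source_profiles)
  if (all(ids %in% srcs))
    return(rowMeans(truth$source_profiles[, ids, drop = FALSE]))
  if (!all(ids %in% colnames(truth$profile)))
    stop("unknown member sample(s): ",
         paste(setdiff(ids, colnames(truth$profile)), collapse = ", "),
         call. = FALSE)
  if (any(truth$roles[ids] != "biological"))
    stop("pool members must be biological samples", call. = FALSE)
  rowMeans(truth$profile[, ids, drop = FALSE])
}

#' Inject additive and multiplicative batch effects
#'
#' Utility for correction benchmarks: draws, per (batch, probe), an additive
#' shift `N(0, add_sd^2)` and a multiplicative residual scale
#' `LogNormal(0, scale_sd^2)`, and applies `y' = c + gamma + delta * (y - c)`
#' where `c` is the probe's true (or fitted) signal.
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param batch_level batch coordinate at which effects are drawn.
#' @param add_sd SD of the additive shifts (log2 scale).
#' @param scale_sd SD of log scale factors.
#' @param center optional probes x samples matrix of true signal; defaults
#'   to the per-probe grand mean.
#' @param seed integer seed for the draws.
#' @return List with `expression` (the perturbed `expr_matrix`), `additive`
#'   and `scale` (probes x batches matrices of realised effects).
#' @export
inject_batch_effects <- function(m, sheet, batch_level, add_sd = 0.5,
                                 scale_sd = 0.2, center = NULL, seed = 1) {
  check_samples(sheet, m)
  Y <- m$values
  batch <- sheet[[batch_level]][match(colnames(Y), sheet$sample_id)]
  ub <- unique(batch)
  if (is.null(center)) center <- matrix(rowMeans(Y), nrow(Y), ncol(Y))
  set.seed(seed)
  gam <- matrix(stats::rnorm(nrow(Y) * length(ub), 0, add_sd),
                nrow(Y), length(ub), dimnames = list(rownames(Y), ub))
  del <- matrix(exp(stats::rnorm(nrow(Y) * length(ub), 0, scale_sd)),
                nrow(Y), length(ub), dimnames = list(rownames(Y), ub))
  out <- center + gam[, batch, drop = FALSE] +
    del[, batch, drop = FALSE] * (Y - center)
  dimnames(out) <- dimnames(Y)
  list(expression = expression_matrix(out, m$detection),
       additive = gam, scale = del)
}
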