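#' GC-content vs variability enrichment
#'
#' Cross-tabulates probes by (GC fraction below `gc_cut`) x (SD above
#' `sd_cut`) and tests the association with a Pearson chi-squared test
#' without continuity correction. By default the SD cutoff is the 90th
#' percentile of the SD vector, which adapts to the magnitude of each
#' processing level; with a quantile-specified cutoff the result is
#' invariant to strictly monotone transforms of the SD vector.
#'
#' @param sd numeric vector of per-probe SD estimates at one level.
#' @param gc numeric vector of per-probe GC fractions, aligned with `sd`.
#' @param gc_cut GC fraction cutoff (probes below are "low GC").
#' @param sd_cut SD threshold; `NULL` uses `quantile(sd, sd_quantile)`.
#' @param sd_quantile quantile used when `sd_cut` is `NULL`.
#' @return List with `table` (2x2 counts), `statistic`, `p`, the resolved
#'   cutoffs and `reliable` (`FALSE` when any expected cell count is below
#'   5; the result is still returned).
#' @export
gc_sd_enrichment <- function(sd, gc, gc_cut = 0.55, sd_cut = NULL,
                             sd_quantile = 0.9) {
  if (length(sd) != length(gc))
    stop("sd and gc must be aligned on the same probes", call. = FALSE)
  keep <- !is.na(sd) & !is.na(gc)
  sd <- sd[keep]; gc <- gc[keep]
  if (is.null(sd_cut)) sd_cut <- stats::quantile(sd, sd_quantile,
                                                 names = FALSE)
  low_gc <- factor(gc < gc_cut, levels = c(TRUE, FALSE),
                   labels = c("low_gc", "high_gc"))
  high_sd <- factor(sd > sd_cut, levels = c(TRUE, FALSE),
                    labels = c("high_sd", "low_sd"))
  tab <- table(low_gc, high_sd)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("cutoff(s) do not split the probes; choose interior values",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       gc_cut = gc_cut, sd_cut = sd_cut,
       reliable = all(ct$expected >= 5))
}

#' GC distribution of a probe subset against the probe universe
#'
#' Gaussian-kernel smoothed densities of GC fraction for the full probe
#' universe and for a selected subset (e.g. probes consistently
#' batch-regulated), with a chi-squared goodness-of-fit test of the
#' subset's binned counts against the universe proportions (bin width
#' 0.05 over \[0, 1\]).
#'
#' @param selected character vector of probe ids, a subset of the universe.
#' @param universe a `probe_sheet` with `gc_fraction`.
#' @param bandwidth kernel bandwidth for the smoothed densities.
#' @param bin_width bin width for the chi-squared test.
#' @return List with `density_universe`, `density_selected`, `statistic`,
#'   `p` and `underpowered` (`TRUE` when fewer than 20 probes are
#'   selected).
#' @export
gc_distribution_shift <- function(selected, universe, bandwidth = 0.02,
                                  bin_width = 0.05) {
  stopifnot(inherits(universe, "probe_sheet"))
  missing <- setdiff(selected, universe$probe_id)
  if (length(missing))
    stop("selected probes outside the universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  gc_all <- universe$gc_fraction
  gc_sel <- universe$gc_fraction[universe$probe_id %in% selected]
  d_all <- stats::density(gc_all, bw = bandwidth, from = 0, to = 1)
  d_sel <- stats::density(gc_sel, bw = bandwidth, from = 0, to = 1)
  breaks <- seq(0, 1, by = bin_width)
  cnt_all <- table(cut(gc_all, breaks, include.lowest = TRUE))
  cnt_sel <- table(cut(gc_sel, breaks, include.lowest = TRUE))
  keep <- cnt_all > 0
  ct <- suppressWarnings(stats::chisq.test(
    as.vector(cnt_sel[keep]), p = as.vector(cnt_all[keep]) / sum(cnt_all)))
  list(density_universe = d_all, density_selected = d_sel,
       statistic = unname(ct$statistic), p = ct$p.value,
       underpowered = length(gc_sel) < 20L)
}

#' Probe position vs variability association
#'
#' Spearman rank correlation between the probe's position in its target
#' gene (as a fraction of gene length, already strand-normalised) and the
#' per-probe SD, with a two-sided permutation p-value.
#'
#' @param sd numeric vector of per-probe SD estimates.
#' @param probes a `probe_sheet` with `probe_position_fraction`, aligned
#'   with `sd`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations (the global RNG state is
#'   restored afterwards).
#' @return List with `rho`, `p` and `n`.
#' @export
position_sd_association <- function(sd, probes, n_perm = 1000, seed = 1) {
  stopifnot(inherits(probes, "probe_sheet"))
  pos <- probes$probe_position_fraction
  if (is.null(pos))
    stop("probe sheet lacks probe_position_fraction", call. = FALSE)
  keep <- !is.na(sd) & !is.na(pos)
  sd <- sd[keep]; pos <- pos[keep]
  if (length(unique(pos)) < 2L)
    stop("all probe positions identical", call. = FALSE)
  rho <- stats::cor(pos, sd, method = "spearman")
  perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i)
    stats::cor(pos, sample(sd), method = "spearman"), numeric(1L)))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p = p, n = length(sd))
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}
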