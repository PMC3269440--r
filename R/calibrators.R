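#' Per-probe expression shifts between batches
#'
#' For every eligible pair of samples derived from the same source RNA —
#' technical duplicates of biological samples, replicates of the generic
#' control, and replicates of the pooled control — hybridised in two
#' distinct units of `batch_level`, computes the per-probe log2 difference
#' `second batch - first batch`. The orientation is fixed by lexicographic
#' batch label order and applied identically to samples and controls so
#' signs cancel in correlations. Replicate series are linked by
#' `duplicate_id`; pairs of a series with more than two members are
#' enumerated over all cross-batch pairings, and same-batch pairs are
#' skipped with a warning.
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param batch_level batch coordinate the shifts are taken across.
#' @return An object of class `shift_collection`: a list with `delta`
#'   (probes x pairs matrix, probes ordered as in `m`) and `pairs`
#'   (data.frame with `pair_id`, `kind`, `from`, `to`, `sample_from`,
#'   `sample_to`).
#' @export
batch_shifts <- function(m, sheet, batch_level) {
  stopifnot(inherits(m, "expr_matrix"))
  check_samples(sheet, m)
  df <- as.data.frame(sheet)
  df <- df[df$sample_id %in% colnames(m$values), , drop = FALSE]
  df$batch <- df[[batch_level]]
  kind_of <- function(role) switch(role,
                                   biological = "sample_duplicate",
                                   generic_control = "generic_control",
                                   pooled_control = "pooled_control")
  pair_rows <- list()
  for (id in unique(stats::na.omit(df$duplicate_id))) {
    members <- df[!is.na(df$duplicate_id) & df$duplicate_id == id, ,
                  drop = FALSE]
    if (nrow(members) < 2L) next
    combs <- utils::combn(nrow(members), 2L)
    n_cross <- 0L
    for (cc in seq_len(ncol(combs))) {
      a <- members[combs[1L, cc], ]
      b <- members[combs[2L, cc], ]
      if (a$batch == b$batch) next
      n_cross <- n_cross + 1L
      if (a$batch > b$batch) { tmp <- a; a <- b; b <- tmp }
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s:%s>%s", id, a$batch, b$batch),
        kind = kind_of(a$role), from = a$batch, to = b$batch,
        sample_from = a$sample_id, sample_to = b$sample_id,
        stringsAsFactors = FALSE)
    }
    if (n_cross == 0L)
      warning("duplicate series '", id, "' spans a single ", batch_level,
              "; skipped", call. = FALSE)
  }
  if (!length(pair_rows))
    return(structure(list(delta = matrix(numeric(0), nrow(m$values), 0L,
                                         dimnames = list(rownames(m$values),
                                                         NULL)),
                          pairs = data.frame()),
                     class = "shift_collection"))
  pairs <- do.call(rbind, pair_rows)
  delta <- m$values[, pairs$sample_to, drop = FALSE] -
    m$values[, pairs$sample_from, drop = FALSE]
  colnames(delta) <- pairs$pair_id
  structure(list(delta = delta, pairs = pairs),
            class = "shift_collection")
}

#' @export
print.shift_collection <- function(x, ...) {
  cat(sprintf("shift_collection: %d probes x %d pairs\n", nrow(x$delta),
              nrow(x$pairs)))
  if (nrow(x$pairs)) print(table(x$pairs$kind))
  invisible(x)
}

#' Fidelity of a control's batch shift to a sample's batch shift
#'
#' Pearson correlation (as a percentage) between a control replicate pair's
#' per-probe shift and a duplicate sample pair's shift across the same two
#' batches, overall and restricted to probes whose absolute sample shift
#' exceeds each magnitude threshold (how well the calibrator tracks the
#' batch effect grows with the size of the shift).
#'
#' @param control_delta numeric vector: control pair per-probe shifts.
#' @param sample_delta numeric vector, same probe universe and order.
#' @param magnitude_bins cumulative |sample shift| thresholds in log2 units.
#' @return Named numeric vector of correlations (percent) per threshold;
#'   `NA` where a bin holds fewer than 3 probes.
#' @export
calibrator_fidelity <- function(control_delta, sample_delta,
                                magnitude_bins = c(0, 0.5, 1, 1.5)) {
  if (length(control_delta) != length(sample_delta))
    stop("shift vectors must share the probe universe", call. = FALSE)
  out <- stats::setNames(rep(NA_real_, length(magnitude_bins)),
                         paste0("gt_", magnitude_bins))
  for (i in seq_along(magnitude_bins)) {
    keep <- abs(sample_delta) > magnitude_bins[i]
    if (sum(keep) >= 3L)
      out[i] <- 100 * stats::cor(control_delta[keep], sample_delta[keep])
  }
  out
}

#' Per-pair fidelity table over a shift collection
#'
#' For every duplicate-sample pair, correlates its shift with every control
#' replicate pair spanning the same two batches and averages within control
#' kind, at each magnitude threshold.
#'
#' @param shifts a `shift_collection` from [batch_shifts()].
#' @param magnitude_bins cumulative |sample shift| thresholds.
#' @return data.frame with columns `pair_id`, `kind`, `threshold`, `r_pct`,
#'   `n_control_pairs`.
#' @export
fidelity_table <- function(shifts, magnitude_bins = c(0, 0.5, 1, 1.5)) {
  stopifnot(inherits(shifts, "shift_collection"))
  pr <- shifts$pairs
  samp <- which(pr$kind == "sample_duplicate")
  rows <- list()
  for (s in samp) {
    sd_vec <- shifts$delta[, s]
    for (kind in c("generic_control", "pooled_control")) {
      ctrl <- which(pr$kind == kind & pr$from == pr$from[s] &
                      pr$to == pr$to[s])
      if (!length(ctrl)) next
      fid <- vapply(ctrl, function(cc)
        calibrator_fidelity(shifts$delta[, cc], sd_vec, magnitude_bins),
        numeric(length(magnitude_bins)))
      fid <- rowMeans(matrix(fid, nrow = length(magnitude_bins)),
                      na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pr$pair_id[s], kind = kind,
        threshold = magnitude_bins, r_pct = unname(fid),
        n_control_pairs = length(ctrl), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Paired comparison of two calibrator types
#'
#' One-sample, two-tailed t-test on the per-pair fidelity differences
#' `a - b` (e.g. pooled minus generic control, over the same duplicate
#' sample pairs).
#'
#' @param fidelities_a,fidelities_b paired numeric vectors of fidelities
#'   (percent), same duplicate pairs in the same order.
#' @return List with `mean_difference` (percent points), `p`, `n`, and
#'   `degenerate` (`TRUE` when the differences have zero variance, where
#'   the t statistic is undefined unless the mean is also zero).
#' @export
compare_calibrators <- function(fidelities_a, fidelities_b) {
  if (length(fidelities_a) != length(fidelities_b))
    stop("fidelity lists must be paired", call. = FALSE)
  d <- fidelities_a - fidelities_b
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(mean_difference = mean(d),
                p = if (mean(d) == 0) 1 else NA_real_,
                n = length(d), degenerate = mean(d) != 0))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(mean_difference = unname(tt$estimate), p = tt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Probes regulated by the batch effect
#'
#' A probe counts as batch-regulated when its absolute shift exceeds
#' `log2(fold_threshold)` (strictly) in at least `min_pairs` of the
#' duplicate sample pairs; `min_pairs = 1` reads as "in any pair".
#'
#' @param shifts a `shift_collection`.
#' @param fold_threshold natural-scale fold change, must exceed 1.
#' @param min_pairs minimum number of qualifying duplicate pairs.
#' @return Character vector of probe ids.
#' @export
count_batch_regulated <- function(shifts, fold_threshold = 2,
                                  min_pairs = 1) {
  stopifnot(inherits(shifts, "shift_collection"))
  if (fold_threshold <= 1)
    stop("fold_threshold must be > 1", call. = FALSE)
  samp <- shifts$pairs$kind == "sample_duplicate"
  if (!any(samp)) stop("no duplicate sample pairs", call. = FALSE)
  hits <- rowSums(abs(shifts$delta[, samp, drop = FALSE]) >
                    log2(fold_threshold))
  rownames(shifts$delta)[hits >= min_pairs]
}
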