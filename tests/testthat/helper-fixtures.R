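# Small in-code fixtures shared across test files.

toy_matrix <- function(values, probe_ids = NULL, sample_ids = NULL,
                       detection = NULL) {
  if (is.null(probe_ids)) probe_ids <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(probe_ids, sample_ids)
  if (!is.null(detection)) dimnames(detection) <- dimnames(values)
  expression_matrix(values, detection)
}

## Minimal sheet: one batch level "batch", all biological, optional groups.
toy_sheet <- function(sample_ids, batch, group = NA_character_,
                      duplicate_id = NA_character_, role = "biological",
                      extra = NULL) {
  df <- data.frame(sample_id = sample_ids, role = role, group = group,
                   duplicate_id = duplicate_id, batch = as.character(batch),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  sample_sheet(df, batch_levels = "batch")
}

## Balanced nested sheet for variance tests: named children counts,
## outermost first, last entry = observations per innermost unit.
nested_sheet <- function(counts, group = NULL) {
  lv <- head(names(counts), -1L)
  n <- prod(counts)
  labs <- list()
  reps <- n
  for (i in seq_along(lv)) {
    units_so_far <- prod(counts[seq_len(i)])
    reps <- n / units_so_far
    idx <- rep(seq_len(units_so_far), each = reps)
    labs[[lv[i]]] <- sprintf("%s%02d", toupper(substr(lv[i], 1, 1)), idx)
  }
  df <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                   role = "biological", group = NA_character_,
                   duplicate_id = NA_character_,
                   stringsAsFactors = FALSE)
  for (l in lv) df[[l]] <- labs[[l]]
  if (!is.null(group))
    df$group <- rep_len(group, n)
  sample_sheet(df, batch_levels = lv)
}

## Draw one matrix from the plain balanced nested Gaussian model (the
## independent generative oracle used against the variance fitters).
draw_nested <- function(G, counts, level_sd, residual_sd,
                        group_effect = NULL, sheet = NULL) {
  if (is.null(sheet)) sheet <- nested_sheet(counts)
  lv <- head(names(counts), -1L)
  n <- nrow(sheet)
  Y <- matrix(rnorm(G * n, 0, residual_sd), G, n,
              dimnames = list(sprintf("p%04d", seq_len(G)),
                              sheet$sample_id))
  for (l in lv) {
    f <- factor(sheet[[l]], levels = unique(sheet[[l]]))
    b <- matrix(rnorm(G * nlevels(f), 0, level_sd[[l]]), G, nlevels(f))
    Y <- Y + b[, as.integer(f), drop = FALSE]
  }
  if (!is.null(group_effect)) {
    g2 <- sheet$group == unique(sheet$group)[2L]
    Y[, g2] <- Y[, g2] + group_effect
  }
  list(m = toy_matrix(Y, sample_ids = sheet$sample_id), sheet = sheet)
}
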