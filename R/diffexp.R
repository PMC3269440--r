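#' Simplified differential expression test
#'
#' Per-probe two-sample Welch t-test (or paired t-test) between two
#' biological groups, with Benjamini-Hochberg adjustment over all tested
#' probes. A probe is called significant when it passes both a minimum
#' natural-scale fold change (`|2^lfc| >= fc_min`, symmetric for
#' down-regulation) and a maximum adjusted p-value. Only biological samples
#' are used, and when a source RNA appears on several arrays (technical
#' duplicates) only its first array is kept, to avoid pseudo-replication.
#'
#' @param m an `expr_matrix`.
#' @param sheet a `sample_sheet` covering `m`'s samples.
#' @param design `"two_group"` (Welch) or `"paired"`.
#' @param fc_min minimum natural-scale fold change.
#' @param p_max maximum BH-adjusted p-value.
#' @param pair_col sample-sheet column pairing subjects in the paired
#'   design; complete pairs are required.
#' @param groups optional length-2 character vector fixing the group order
#'   (reference first); defaults to alphabetical.
#' @return An object of class `de_result`: data.frame with `probe_id`,
#'   `lfc` (log2 fold change, second group minus first), `t`, `df`, `p`,
#'   `p_adj`, `significant`; groups carried as an attribute.
#' @export
de_test <- function(m, sheet, design = c("two_group", "paired"),
                    fc_min = 1.5, p_max = 0.01, pair_col = "subject",
                    groups = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(m, "expr_matrix"))
  check_samples(sheet, m)
  df <- as.data.frame(sheet)
  df <- df[match(colnames(m$values), df$sample_id), , drop = FALSE]
  bio <- df$role == "biological" & !is.na(df$group)
  df <- df[bio, , drop = FALSE]
  if (any(!is.na(df$duplicate_id))) {
    keep <- !duplicated(ifelse(is.na(df$duplicate_id),
                               df$sample_id, df$duplicate_id))
    df <- df[keep, , drop = FALSE]
  }
  found <- sort(unique(df$group))
  if (length(found) != 2L)
    stop("need exactly 2 biological groups, found: ",
         paste(found, collapse = ", "), call. = FALSE)
  if (is.null(groups)) groups <- found
  else if (!setequal(groups, found))
    stop("`groups` must name the two groups present", call. = FALSE)
  Y <- m$values[, df$sample_id, drop = FALSE]
  g1 <- df$group == groups[1L]
  g2 <- df$group == groups[2L]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)

  if (design == "two_group") {
    n1 <- sum(g1); n2 <- sum(g2)
    m1 <- rowMeans(Y[, g1, drop = FALSE])
    m2 <- rowMeans(Y[, g2, drop = FALSE])
    v1 <- rowSums((Y[, g1, drop = FALSE] - m1)^2) / (n1 - 1L)
    v2 <- rowSums((Y[, g2, drop = FALSE] - m2)^2) / (n2 - 1L)
    lfc <- m2 - m1
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    dfree <- ifelse(se2 > 0,
                    se2^2 / ((v1 / n1)^2 / (n1 - 1L) +
                               (v2 / n2)^2 / (n2 - 1L)),
                    n1 + n2 - 2L)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), dfree),
                ifelse(lfc == 0, 1, 0))
  } else {
    if (!pair_col %in% colnames(df))
      stop("paired design needs a '", pair_col, "' column", call. = FALSE)
    subj <- df[[pair_col]]
    tab <- table(subj, df$group)
    incomplete <- rownames(tab)[rowSums(tab >= 1L) < 2L | rowSums(tab) != 2L]
    if (length(incomplete))
      stop("incomplete pair(s) for subject(s): ",
           paste(incomplete, collapse = ", "), call. = FALSE)
    subjects <- rownames(tab)
    a <- df$sample_id[match(paste(subjects, groups[1L]),
                            paste(subj, df$group))]
    b <- df$sample_id[match(paste(subjects, groups[2L]),
                            paste(subj, df$group))]
    D <- Y[, b, drop = FALSE] - Y[, a, drop = FALSE]
    n <- ncol(D)
    lfc <- rowMeans(D)
    vd <- rowSums((D - lfc)^2) / (n - 1L)
    tt <- ifelse(vd > 0, lfc / sqrt(vd / n), 0)
    dfree <- rep(n - 1L, length(lfc))
    p <- ifelse(vd > 0, 2 * stats::pt(-abs(tt), dfree),
                ifelse(lfc == 0, 1, 0))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  sig <- abs(lfc) >= log2(fc_min) & p_adj <= p_max
  res <- data.frame(probe_id = rownames(Y), lfc = lfc, t = tt, df = dfree,
                    p = p, p_adj = p_adj, significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("de_result", "data.frame"),
            groups = groups, design = design)
}

#' Significant probe ids of a DE result
#'
#' @param res a `de_result`.
#' @return Character vector of significant probe ids.
#' @export
significant_probes <- function(res) {
  stopifnot(inherits(res, "de_result"))
  res$probe_id[res$significant]
}

#' Concordance between differential-expression lists
#'
#' Pairwise intersection sizes and the full common intersection across a
#' collection of probe id sets (e.g. DE lists from replicate experiments or
#' from different correction regimes).
#'
#' @param lists named list (>= 2) of character vectors of probe ids.
#' @return List with `pairwise` (symmetric matrix of intersection sizes,
#'   diagonal = list sizes), `common` (ids in every list) and `n_common`.
#' @export
list_concordance <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least 2 lists", call. = FALSE)
  if (is.null(names(lists)))
    names(lists) <- paste0("list", seq_along(lists))
  k <- length(lists)
  pw <- matrix(0L, k, k, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      pw[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  common <- Reduce(intersect, lists)
  list(pairwise = pw, common = common, n_common = length(common))
}
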