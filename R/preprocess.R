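#' Detection filtering of probes
#'
#' A probe is removed when its detection confidence is less than or equal to
#' `conf_threshold` in strictly more than `max_fail_fraction` of the
#' samples; probes failing in exactly that fraction are retained. Filtering
#' is intended to run before quantile normalisation. Detection confidence is
#' read as "larger is better".
#'
#' @param m an `expr_matrix` with a detection grid.
#' @param conf_threshold confidence at or below which a sample counts as a
#'   failure (default 0.95).
#' @param max_fail_fraction largest tolerated fraction of failing samples
#'   (default 0.20).
#' @return List with `expression` (the filtered `expr_matrix`, original
#'   probe order preserved) and `removed` (character vector of removed probe
#'   ids).
#' @export
detection_filter <- function(m, conf_threshold = 0.95,
                             max_fail_fraction = 0.20) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$detection))
    stop(paste("no detection grid present; to analyse undetected data, skip",
               "detection filtering explicitly rather than calling",
               "detection_filter()"), call. = FALSE)
  fail_frac <- rowMeans(m$detection <= conf_threshold)
  drop <- fail_frac > max_fail_fraction
  list(expression = m[!drop, ], removed = rownames(m$values)[drop])
}

#' Quantile normalisation
#'
#' Forces every sample's value distribution onto a common reference built
#' from rank-wise means: for each rank r the r-th order statistic of every
#' column is replaced by the mean of all columns' r-th order statistics.
#' Tied values receive the mean of the reference values at their tied ranks,
#' which keeps the operation idempotent. Probe order is preserved and the
#' result is deterministic.
#'
#' @param m an `expr_matrix` without missing values.
#' @return The normalised `expr_matrix` (detection grid carried through
#'   unchanged).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (anyNA(m$values))
    stop("missing values present; imputation is out of scope", call. = FALSE)
  if (ncol(m$values) < 1L) stop("need at least one sample", call. = FALSE)
  out <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(out) <- dimnames(m$values)
  expression_matrix(out, m$detection)
}

#' Pairwise Pearson correlations as percentages
#'
#' Pearson product-moment correlation of every pair of sample columns over
#' all retained probes, reported as percentages where 100 is a perfect
#' correlation; the diagonal is exactly 100.
#'
#' @param m an `expr_matrix` with at least 2 probes.
#' @param subset optional character vector of sample ids to restrict to.
#' @return Symmetric numeric matrix of percentages.
#' @export
pairwise_correlation <- function(m, subset = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(v))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    v <- v[, subset, drop = FALSE]
  }
  if (ncol(v) < 2L || nrow(v) < 2L)
    stop("need at least 2 samples and 2 probes", call. = FALSE)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  r <- 100 * stats::cor(v)
  diag(r) <- 100
  r
}
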