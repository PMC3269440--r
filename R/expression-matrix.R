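#' Construct an expression matrix container
#'
#' An `expr_matrix` holds a probes x samples grid of log2 intensities plus an
#' optional grid of detection confidences in \[0, 1\] with identical
#' dimensions. Probe and sample identifiers are carried as dimnames and must
#' be unique.
#'
#' @param values numeric matrix of log2 intensities with unique rownames
#'   (probe ids) and colnames (sample ids).
#' @param detection optional numeric matrix of detection confidences in
#'   \[0, 1\] with identical dimnames.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `detection`.
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2"))))
#' dim(m)
#' @export
expression_matrix <- function(values, detection = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L)
      stop("`values` must carry probe ids as rownames", call. = FALSE)
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0L)
      stop("`values` must carry sample ids as colnames", call. = FALSE)
    colnames(values) <- character(0)
  }
  check_unique_ids(rownames(values), "probe")
  check_unique_ids(colnames(values), "sample")
  if (!is.null(detection)) {
    if (!is.matrix(detection) || !is.numeric(detection))
      stop("`detection` must be a numeric matrix", call. = FALSE)
    check_same_ids(rownames(values), rownames(detection), "probe")
    check_same_ids(colnames(values), colnames(detection), "sample")
    detection <- detection[rownames(values), colnames(values), drop = FALSE]
    if (anyNA(detection) || any(detection < 0) || any(detection > 1))
      stop("detection confidences must lie in [0, 1] with no missing values",
           call. = FALSE)
  }
  structure(list(values = values, detection = detection),
            class = "expr_matrix")
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  invisible(ids)
}

check_same_ids <- function(expected, got, what) {
  extra <- setdiff(got, expected)
  missing <- setdiff(expected, got)
  if (length(extra) || length(missing))
    stop(sprintf(
      "%s ids differ between expression and detection grids%s%s", what,
      if (length(extra)) paste0("; unexpected: ",
                                paste(utils::head(extra, 5), collapse = ", "))
      else "",
      if (length(missing)) paste0("; absent: ",
                                  paste(utils::head(missing, 5), collapse = ", "))
      else ""), call. = FALSE)
  invisible(got)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Subset an expression matrix
#'
#' Row (probe) and column (sample) subsetting keeps the detection grid, when
#' present, aligned with the value grid.
#'
#' @param x an `expr_matrix`.
#' @param i,j probe / sample indices or ids.
#' @param ... ignored.
#' @return An `expr_matrix` restricted to the requested probes and samples.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE],
                    if (!is.null(x$detection))
                      x$detection[i, j, drop = FALSE])
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$detection)) " (with detection confidences)"
              else ""))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' The file must be TSV with a `probe_id` first column and one column per
#' sample; an optional detection file must share exactly the same probe and
#' sample ids.
#'
#' @param path path to the TSV of log2 intensities.
#' @param detection_path optional path to a TSV of detection confidences.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, detection_path = NULL) {
  values <- read_numeric_grid(path)
  detection <- if (!is.null(detection_path)) read_numeric_grid(detection_path)
  expression_matrix(values, detection)
}

read_numeric_grid <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("no columns found in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  check_unique_ids(ids, "probe")
  body <- df[, -1L, drop = FALSE]
  check_unique_ids(colnames(body), "sample")
  if (nrow(body) == 0L)
    body[] <- lapply(body, as.numeric)
  bad <- !vapply(body, is.numeric, logical(1L))
  if (any(bad))
    stop("non-numeric body cells in column(s): ",
         paste(colnames(body)[bad], collapse = ", "), call. = FALSE)
  m <- if (nrow(body) == 0L)
    matrix(numeric(0), 0L, ncol(body),
           dimnames = list(character(0), colnames(body)))
  else as.matrix(body)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip reproduces the matrix to better than 1e-12 relative.
#'
#' @param m an `expr_matrix`.
#' @param path output path for the value grid.
#' @param detection_path optional output path for the detection grid.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path, detection_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  write_numeric_grid(m$values, path)
  if (!is.null(detection_path)) {
    if (is.null(m$detection))
      stop("matrix carries no detection grid", call. = FALSE)
    write_numeric_grid(m$detection, detection_path)
  }
  invisible(path)
}

write_numeric_grid <- function(values, path) {
  if (nrow(values) == 0L) {
    writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"),
               path)
    return(invisible(path))
  }
  df <- data.frame(probe_id = rownames(values),
                   signif(values, 15L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
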