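#' Construct and validate a sample sheet
#'
#' A sample sheet assigns every array (one sample per array) a role, an
#' optional biological group, an optional duplicate identifier linking
#' technical duplicates of one source RNA, and a set of strictly nested
#' batch coordinates ordered from outermost to innermost (for example
#' experiment, run, chip).
#'
#' Strict nesting means every unit label at an inner level occurs under
#' exactly one unit of the level above it; control samples (roles other than
#' `"biological"`) must not carry a biological group.
#'
#' @param df data.frame with columns `sample_id`, `role`, `group`,
#'   `duplicate_id` and one column per batch level.
#' @param batch_levels character vector of batch coordinate column names,
#'   outermost first.
#' @return The validated data.frame with class `sample_sheet` and attribute
#'   `batch_levels`.
#' @export
sample_sheet <- function(df, batch_levels) {
  stopifnot(is.data.frame(df), is.character(batch_levels),
            length(batch_levels) >= 1L)
  required <- c("sample_id", "role", "group", "duplicate_id", batch_levels)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  check_unique_ids(df$sample_id, "sample")
  ok_roles <- c("biological", "generic_control", "pooled_control")
  bad <- setdiff(unique(df$role), ok_roles)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ctrl <- df$role != "biological" & !is.na(df$group)
  if (any(ctrl))
    stop("control samples must have no biological group: ",
         paste(utils::head(df$sample_id[ctrl], 5), collapse = ", "),
         call. = FALSE)
  for (lv in batch_levels) df[[lv]] <- as.character(df[[lv]])
  check_nesting(df, batch_levels)
  structure(df, class = c("sample_sheet", "data.frame"),
            batch_levels = batch_levels)
}

check_nesting <- function(df, batch_levels) {
  if (length(batch_levels) < 2L) return(invisible(TRUE))
  for (i in seq_len(length(batch_levels) - 1L)) {
    outer <- batch_levels[i]
    inner <- batch_levels[i + 1L]
    n_parents <- tapply(df[[outer]], df[[inner]],
                        function(x) length(unique(x)))
    bad <- names(n_parents)[n_parents > 1L]
    if (length(bad))
      stop(sprintf("batch level '%s' is not nested in '%s': unit(s) %s occur under more than one parent",
                   inner, outer, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Batch levels of a sample sheet
#'
#' @param sheet a `sample_sheet`.
#' @return Character vector of batch coordinate names, outermost first.
#' @export
batch_levels <- function(sheet) attr(sheet, "batch_levels")

#' Check a sample sheet against an expression matrix
#'
#' Every sample id of the matrix must appear exactly once in the sheet.
#'
#' @param sheet a `sample_sheet`.
#' @param m an `expr_matrix`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_samples <- function(sheet, m) {
  ids <- colnames(m$values)
  missing <- setdiff(ids, sheet$sample_id)
  if (length(missing))
    stop("sample sheet lacks sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read / write sample sheets as TSV
#'
#' Columns are written unquoted in the order `sample_id`, `role`, `group`,
#' `duplicate_id`, then the batch coordinates outermost first; on reading,
#' any columns after the four standard ones are taken as the batch levels
#' unless given explicitly.
#'
#' @param path TSV path.
#' @param batch_levels optional explicit batch level names.
#' @return `read_sample_sheet` returns a `sample_sheet`;
#'   `write_sample_sheet` invisibly returns `path`.
#' @export
read_sample_sheet <- function(path, batch_levels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  df$group[df$group == "NA"] <- NA_character_
  df$duplicate_id[df$duplicate_id == "NA"] <- NA_character_
  std <- c("sample_id", "role", "group", "duplicate_id")
  if (is.null(batch_levels)) batch_levels <- setdiff(colnames(df), std)
  sample_sheet(df, batch_levels)
}

#' @param sheet a `sample_sheet`.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  lv <- batch_levels(sheet)
  df <- as.data.frame(sheet)[, c("sample_id", "role", "group",
                                 "duplicate_id", lv)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a probe sheet
#'
#' Probe annotation: sequence (over A, C, G, T, N), GC fraction, and optional
#' gene mapping columns (`gene_id`, `strand`, `probe_position_fraction`,
#' `n_transcripts`, `n_exons`). Coordinates, when supplied upstream, are
#' taken to be 0-based half-open and the position fraction is expressed on
#' the sense strand of the gene (antisense probes flipped as
#' `1 - raw fraction`).
#'
#' @param df data.frame with at least `probe_id`; `gc_fraction` is recomputed
#'   from `sequence` when both are present and must then agree.
#' @return The validated data.frame with class `probe_sheet`.
#' @export
probe_sheet <- function(df) {
  stopifnot(is.data.frame(df), "probe_id" %in% colnames(df))
  df$probe_id <- as.character(df$probe_id)
  check_unique_ids(df$probe_id, "probe")
  if (!is.null(df$sequence)) {
    df$sequence <- toupper(as.character(df$sequence))
    if (any(!nzchar(df$sequence)))
      stop("empty probe sequence(s)", call. = FALSE)
    bad <- grepl("[^ACGTN]", df$sequence)
    if (any(bad))
      stop("sequences contain characters outside {A,C,G,T,N}: ",
           paste(utils::head(df$probe_id[bad], 5), collapse = ", "),
           call. = FALSE)
    gc <- gc_fraction(df$sequence)
    if (!is.null(df$gc_fraction)) {
      off <- which(abs(df$gc_fraction - gc) > 1e-8)
      if (length(off))
        stop("gc_fraction disagrees with sequence for: ",
             paste(utils::head(df$probe_id[off], 5), collapse = ", "),
             call. = FALSE)
    }
    df$gc_fraction <- gc
  }
  if (!is.null(df$probe_position_fraction)) {
    ppf <- df$probe_position_fraction
    if (any(!is.na(ppf) & (ppf < 0 | ppf > 1)))
      stop("probe_position_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(df$strand)) {
    bad <- setdiff(unique(stats::na.omit(df$strand)), c("+", "-"))
    if (length(bad)) stop("strand must be '+' or '-'", call. = FALSE)
  }
  structure(df, class = c("probe_sheet", "data.frame"))
}

#' GC fraction of DNA sequences
#'
#' Proportion of G+C bases; `N` bases are excluded from both numerator and
#' denominator so ambiguous calls do not bias the fraction.
#'
#' @param sequence character vector of DNA sequences over A, C, G, T, N.
#' @return Numeric vector of GC fractions in \[0, 1\] (`NaN` for all-N
#'   sequences).
#' @examples
#' gc_fraction(c("GGCC", "ATAT", "ATGCN"))
#' @export
gc_fraction <- function(sequence) {
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGTN]", sequence)))
    stop("sequences contain characters outside {A,C,G,T,N}", call. = FALSE)
  dss <- Biostrings::DNAStringSet(sequence)
  freq <- Biostrings::letterFrequency(dss, c("G", "C", "N"))
  gc <- freq[, "G"] + freq[, "C"]
  denom <- Biostrings::width(dss) - freq[, "N"]
  unname(gc / denom)
}

#' Read probe sequences from FASTA
#'
#' Record ids become probe ids; sequences are upper-cased and the GC fraction
#' is computed per record (N excluded from the denominator).
#'
#' @param path FASTA path.
#' @return A `probe_sheet` with columns `probe_id`, `sequence`,
#'   `gc_fraction`.
#' @export
read_probe_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  check_unique_ids(ids, "probe")
  if (any(Biostrings::width(dss) == 0L))
    stop("empty sequence for probe(s): ",
         paste(ids[Biostrings::width(dss) == 0L], collapse = ", "),
         call. = FALSE)
  probe_sheet(data.frame(probe_id = ids,
                         sequence = as.character(dss),
                         stringsAsFactors = FALSE))
}

#' Write probe sequences as FASTA
#'
#' @param probes a `probe_sheet` with a `sequence` column.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_probe_fasta <- function(probes, path) {
  stopifnot(!is.null(probes$sequence))
  dss <- Biostrings::DNAStringSet(probes$sequence)
  names(dss) <- probes$probe_id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read / write probe annotation as TSV
#'
#' @param path TSV path.
#' @return `read_probe_sheet` returns a `probe_sheet`; `write_probe_sheet`
#'   invisibly returns `path`.
#' @export
read_probe_sheet <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  probe_sheet(df)
}

#' @param probes a `probe_sheet`.
#' @rdname read_probe_sheet
#' @export
write_probe_sheet <- function(probes, path) {
  utils::write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
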