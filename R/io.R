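#' Read an f0 contour from CSV
#'
#' The CSV dialect carries explicit voicing: columns `time_s`, `f0_hz` and
#' `voiced` (0/1), header required. Unvoiced rows may carry `f0_hz = 0` or an
#' empty field.
#'
#' @inheritParams read_pitchtier
#' @return An [f0_contour()].
#' @export
read_contour_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "f0_hz", "voiced")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("contour CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  voiced <- as.logical(as.integer(df$voiced))
  f0 <- as.numeric(df$f0_hz)
  f0[!voiced & is.na(f0)] <- 0
  if (any(voiced & (is.na(f0) | f0 <= 0))) {
    bad <- which(voiced & (is.na(f0) | f0 <= 0))[1L]
    stop("contour CSV '", path, "': non-positive f0 on voiced row ", bad,
         call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("non-monotone time axis in '", path, "'", call. = FALSE)
  }
  .contour_with_metadata(df$time_s, f0, voiced, metadata,
                         default_id = .file_stem(path))
}

#' Write an f0 contour to CSV
#'
#' Full double precision is written so that a write/read cycle reproduces the
#' contour bit-identically.
#'
#' @param contour An [f0_contour()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(time_s = formatC(contour$times, digits = 17, format = "g"),
                   f0_hz = formatC(contour$f0_hz, digits = 17, format = "g"),
                   voiced = as.integer(contour$voiced))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vocalization metadata table
#'
#' One row per vocalization: `vocalization_id`, `infant_id`, `sex`,
#' `age_days`, `voc_type`, optional `manual_no_pattern` (0/1).
#'
#' @param path Path to a CSV file.
#' @return A data frame keyed by `vocalization_id`.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vocalization_id", "infant_id", "sex", "age_days", "voc_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$vocalization_id)) {
    stop("metadata CSV '", path, "': duplicated vocalization_id", call. = FALSE)
  }
  if (is.null(df$manual_no_pattern)) {
    df$manual_no_pattern <- integer(nrow(df))
  }
  df$manual_no_pattern <- as.logical(df$manual_no_pattern)
  df
}

#' Write a vocalization metadata table
#'
#' @param corpus A `melody_corpus` or list of [f0_contour()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(corpus, path) {
  contours <- if (inherits(corpus, "melody_corpus")) corpus$contours else corpus
  df <- do.call(rbind, lapply(contours, function(ct) {
    data.frame(vocalization_id = ct$vocalization_id, infant_id = ct$infant_id,
               sex = ct$sex, age_days = ct$age_days, voc_type = ct$voc_type,
               manual_no_pattern = as.integer(ct$manual_no_pattern))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.classification_cols <- c("vocalization_id", "infant_id", "age_days",
                          "age_months", "voc_type", "included",
                          "exclusion_reason", "n_arcs", "n_segmentations",
                          "category", "complexity")

#' Write a per-vocalization classification table
#'
#' Tab-separated, UTF-8, '.' decimal separator; one row per vocalization in
#' input order. An empty input yields a header-only file.
#'
#' @param classifications A data frame as returned by [classify_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(classifications, path) {
  df <- as.data.frame(classifications)[, .classification_cols, drop = FALSE]
  df$included <- as.integer(df$included)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a classification table written by [write_classification_table()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with logical `included` and integer counts.
#' @export
read_classification_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.classification_cols, names(df))
  if (length(miss)) {
    stop("classification table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$included <- as.logical(df$included)
  df
}
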