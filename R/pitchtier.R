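#' Read a PRAAT PitchTier file
#'
#' Parses both PitchTier text dialects: the full format (`points: size = n`
#' with `number =`/`value =` lines) and the short format (bare numbers).
#' PitchTier stores voiced points only, so the returned contour is voiced at
#' every sample; unvoiced gaps are recovered downstream from inter-point
#' spacing.
#'
#' @param path Path to the PitchTier file.
#' @param metadata Optional single-row data frame (or named list) carrying
#'   `vocalization_id`, `infant_id`, `sex`, `age_days`, `voc_type` and
#'   optionally `manual_no_pattern`, e.g. one row of [read_metadata_csv()]
#'   output. When `NULL`, the file stem is used as both vocalization and
#'   infant id with placeholder metadata.
#' @return An [f0_contour()].
#' @export
read_pitchtier <- function(path, metadata = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 2L || !grepl("ooTextFile", lines[1L]) ||
      !grepl("PitchTier", lines[2L])) {
    stop("malformed PitchTier header in '", path,
         "' (line 1-2): expected ooTextFile / PitchTier", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (any(grepl("^points:\\s*size", body)) || any(grepl("^number\\s*=", body))) {
    pts <- .parse_pitchtier_full(body, path)
  } else {
    pts <- .parse_pitchtier_short(body, path)
  }
  if (nrow(pts) == 0L) {
    stop("empty tier in '", path, "': no pitch points", call. = FALSE)
  }
  if (any(diff(pts$time) <= 0)) {
    i <- which(diff(pts$time) <= 0)[1L] + 1L
    stop("non-monotone time axis in '", path, "' at point ", i, call. = FALSE)
  }
  .contour_with_metadata(pts$time, pts$f0, rep(TRUE, nrow(pts)),
                         metadata, default_id = .file_stem(path))
}

.parse_pitchtier_full <- function(body, path) {
  num <- function(key, line) {
    m <- regmatches(line, regexec(paste0(key, "\\s*=\\s*([-0-9.eE+]+)"), line))[[1L]]
    if (length(m) < 2L) return(NA_real_)
    as.numeric(m[2L])
  }
  size_line <- grep("^points:\\s*size\\s*=", body, value = TRUE)
  if (!length(size_line)) {
    stop("malformed PitchTier in '", path, "': missing 'points: size' line",
         call. = FALSE)
  }
  n <- num("size", size_line[1L])
  tt <- vapply(grep("^number\\s*=", body, value = TRUE), num, 0, key = "number",
               USE.NAMES = FALSE)
  ff <- vapply(grep("^value\\s*=", body, value = TRUE), num, 0, key = "value",
               USE.NAMES = FALSE)
  if (length(tt) != length(ff) || length(tt) != n) {
    stop("malformed PitchTier in '", path, "': declared ", n,
         " points, found ", length(tt), " times / ", length(ff), " values",
         call. = FALSE)
  }
  data.frame(time = tt, f0 = ff)
}

.parse_pitchtier_short <- function(body, path) {
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    stop("malformed short PitchTier in '", path, "': non-numeric line ",
         which(is.na(vals))[1L] + 2L, call. = FALSE)
  }
  if (length(vals) < 3L) {
    stop("malformed short PitchTier in '", path, "': header truncated",
         call. = FALSE)
  }
  n <- vals[3L]
  rest <- vals[-(1:3)]
  if (n == 0L && length(rest) == 0L) {
    return(data.frame(time = numeric(0), f0 = numeric(0)))
  }
  if (length(rest) != 2 * n) {
    stop("malformed short PitchTier in '", path, "': declared ", n,
         " points, found ", length(rest) / 2, call. = FALSE)
  }
  data.frame(time = rest[c(TRUE, FALSE)], f0 = rest[c(FALSE, TRUE)])
}

#' Write a PRAAT PitchTier file
#'
#' Only voiced samples are written (PitchTier has no voicing mask). Times and
#' frequencies are written with six decimals, matching the read/write
#' round-trip guarantee.
#'
#' @param contour An [f0_contour()].
#' @param path Output path.
#' @param format `"short"` (default) or `"full"` PitchTier text dialect.
#' @return `path`, invisibly.
#' @export
write_pitchtier <- function(contour, path, format = c("short", "full")) {
  format <- match.arg(format)
  tt <- contour$times[contour$voiced]
  ff <- contour$f0_hz[contour$voiced]
  n <- length(tt)
  if (n == 0L) stop("cannot write PitchTier: contour has no voiced samples",
                    call. = FALSE)
  xmin <- min(tt); xmax <- max(tt)
  fmt <- function(x) sprintf("%.6f", x)
  if (format == "short") {
    out <- c("File type = \"ooTextFile\"", "Object class = \"PitchTier\"", "",
             fmt(xmin), fmt(xmax), as.character(n),
             as.vector(rbind(fmt(tt), fmt(ff))))
  } else {
    out <- c("File type = \"ooTextFile\"", "Object class = \"PitchTier\"", "",
             paste0("xmin = ", fmt(xmin)), paste0("xmax = ", fmt(xmax)),
             paste0("points: size = ", n),
             unlist(lapply(seq_len(n), function(i) {
               c(sprintf("points [%d]:", i),
                 paste0("    number = ", fmt(tt[i])),
                 paste0("    value = ", fmt(ff[i])))
             })))
  }
  writeLines(out, path)
  invisible(path)
}

.file_stem <- function(path) sub("\\.[A-Za-z0-9]+$", "", basename(path))

.contour_with_metadata <- function(times, f0, voiced, metadata, default_id) {
  md <- list(vocalization_id = default_id, infant_id = default_id,
             sex = "female", age_days = 1L, voc_type = "C",
             manual_no_pattern = FALSE)
  if (!is.null(metadata)) {
    metadata <- as.list(metadata)
    for (k in names(md)) if (!is.null(metadata[[k]])) md[[k]] <- metadata[[k]]
  }
  f0_contour(times = times, f0_hz = f0, voiced = voiced,
             vocalization_id = md$vocalization_id, infant_id = md$infant_id,
             sex = md$sex, age_days = md$age_days, voc_type = md$voc_type,
             manual_no_pattern = md$manual_no_pattern)
}
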