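#' Construct an f0 contour
#'
#' An `f0_contour` holds one vocalization's fundamental-frequency track plus
#' its metadata. A vocalization is the total vocal output of a single
#' expiration; its time-varying f0 is the melody analysed by the rest of the
#' package.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param f0_hz Fundamental frequency in Hz; must lie in the plausible infant
#'   range 50--1200 Hz wherever `voiced` is `TRUE` (0 or `NA` allowed on
#'   unvoiced samples).
#' @param voiced Logical voicing mask aligned with `times`.
#' @param vocalization_id,infant_id Identifier strings.
#' @param sex `"female"` or `"male"`.
#' @param age_days Age at recording, in days (>= 1). Age in months is derived
#'   in 30-day bins, `floor((age_days - 1)/30) + 1`, clamped to 1..12 so the
#'   final bin absorbs days 331--373.
#' @param voc_type Vocalization type: `"C"` (cry), `"NC"` (early non-cry:
#'   vocants, coos, primitive babbling), `"BM"` (marginal babbling) or `"BC"`
#'   (canonical babbling). `C`/`NC` are coded in months 1--6 only and `BM`/`BC`
#'   in months 7--12 only, mirroring the coding scheme in which babbling
#'   subtypes are differentiated only in the second half-year.
#' @param manual_no_pattern Optional manual exclusion flag for contours judged
#'   unanalysable (phonatory noise, unstable tracking).
#'
#' @return An object of class `f0_contour`.
#' @export
#' @examples
#' ct <- f0_contour(times = c(0, 0.25, 0.5), f0_hz = c(400, 450, 420),
#'                  voiced = c(TRUE, TRUE, TRUE), vocalization_id = "v1",
#'                  infant_id = "i1", sex = "female", age_days = 45,
#'                  voc_type = "C")
#' ct$age_months
f0_contour <- function(times, f0_hz, voiced = rep(TRUE, length(times)),
                       vocalization_id = "voc", infant_id = "infant",
                       sex = c("female", "male"), age_days = 1L,
                       voc_type = c("C", "NC", "BM", "BC"),
                       manual_no_pattern = FALSE) {
  sex <- match.arg(sex)
  voc_type <- match.arg(voc_type)
  times <- as.numeric(times)
  f0_hz <- as.numeric(f0_hz)
  voiced <- as.logical(voiced)
  n <- length(times)
  if (length(f0_hz) != n || length(voiced) != n) {
    stop("times, f0_hz and voiced must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("empty contour", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("non-monotone time axis in contour '", vocalization_id, "'",
         call. = FALSE)
  }
  fv <- f0_hz[voiced]
  if (anyNA(fv) || any(fv < 50 | fv > 1200)) {
    bad <- which(voiced)[which(is.na(fv) | fv < 50 | fv > 1200)[1L]]
    stop("voiced f0 outside plausible infant range [50, 1200] Hz at sample ",
         bad, " (", format(f0_hz[bad]), " Hz) in contour '", vocalization_id,
         "'", call. = FALSE)
  }
  age_days <- as.integer(age_days)
  if (is.na(age_days) || age_days < 1L) {
    stop("age_days must be a positive integer", call. = FALSE)
  }
  am <- age_months_from_days(age_days)
  if (voc_type %in% c("BM", "BC") && am < 7L) {
    stop("voc_type ", voc_type, " requires age_months >= 7 (got month ", am,
         ")", call. = FALSE)
  }
  if (voc_type %in% c("C", "NC") && am > 6L) {
    stop("voc_type ", voc_type, " requires age_months <= 6 (got month ", am,
         ")", call. = FALSE)
  }
  structure(
    list(vocalization_id = as.character(vocalization_id),
         infant_id = as.character(infant_id), sex = sex,
         age_days = age_days, age_months = am, voc_type = voc_type,
         times = times, f0_hz = f0_hz, voiced = voiced,
         manual_no_pattern = isTRUE(manual_no_pattern)),
    class = "f0_contour"
  )
}

#' Convert age in days to the analysis month bin
#'
#' 30-day bins; the final bin is widened to absorb the oldest recordings
#' (days 331--373 all map to month 12).
#'
#' @param age_days Integer vector of ages in days (>= 1).
#' @return Integer month in 1..12.
#' @export
age_months_from_days <- function(age_days) {
  m <- (as.integer(age_days) - 1L) %/% 30L + 1L
  pmin(pmax(m, 1L), 12L)
}

#' @export
print.f0_contour <- function(x, ...) {
  dur <- diff(range(x$times))
  cat(sprintf("f0 contour '%s' (%s, %s, day %d / month %d, type %s)\n",
              x$vocalization_id, x$infant_id, x$sex, x$age_days, x$age_months,
              x$voc_type))
  cat(sprintf("  %d samples over %.3f s, %d voiced (%.0f%%), f0 %s Hz\n",
              length(x$times), dur, sum(x$voiced),
              100 * mean(x$voiced),
              paste(round(range(x$f0_hz[x$voiced])), collapse = "-")))
  if (x$manual_no_pattern) cat("  flagged no-pattern (manual)\n")
  invisible(x)
}

# total voiced duration in seconds: sum of voiced-run spans on the raw samples,
# using the same run-splitting rule as resampling so the inclusion filter and
# the preprocessing agree on what a run is.
voiced_duration <- function(contour, gap_bridge_ms = 20) {
  runs <- voiced_run_spans(contour, gap_bridge_ms)
  if (nrow(runs) == 0L) return(0)
  sum(runs[, 2L] - runs[, 1L])
}

# split the voiced samples of a raw contour into runs; returns a matrix with
# columns t_start, t_end (seconds). A gap between consecutive voiced samples
# splits a run when the spacing exceeds 1.5x the median voiced spacing AND the
# estimated unvoiced stretch (spacing minus one median step) exceeds the
# bridge length. Sub-bridge dropouts are tracker artifacts, not constrictions.
voiced_run_spans <- function(contour, gap_bridge_ms = 20) {
  vt <- contour$times[contour$voiced]
  n <- length(vt)
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  if (n == 1L) return(matrix(c(vt, vt), ncol = 2L))
  dt <- diff(vt)
  med <- stats::median(dt)
  split <- dt > 1.5 * med & (dt - med) > gap_bridge_ms / 1000 + .tol
  starts <- c(1L, which(split) + 1L)
  ends <- c(which(split), n)
  cbind(vt[starts], vt[ends])
}
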