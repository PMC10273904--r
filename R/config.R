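#' Analysis configuration
#'
#' Builds the configuration list consumed by the preprocessing and melody
#' modules. All tunable constants of the pipeline live here so that a run can
#' be reproduced from its resolved configuration alone.
#'
#' @param fs_hz Internal uniform sampling rate of the semitone contour, in Hz.
#'   Must exceed twice `cutoff_hz`.
#' @param cutoff_hz -3 dB cutoff of the Gaussian low-pass applied to the
#'   semitone contour, in Hz. The filter removes high-frequency modulation
#'   noise (tracker jitter, vocal tremor) before arc decomposition.
#' @param f_ref_hz Reference frequency of the semitone scale. Frequency-
#'   modulation amplitudes are semitone *differences*, so the reference cancels
#'   in every arc criterion; it only anchors absolute semitone values for
#'   display and export.
#' @param gap_bridge_ms Unvoiced dropouts up to this length are bridged by
#'   interpolation; longer gaps split the contour into separate voiced runs.
#' @param min_duration_s Minimum melody-arc duration in seconds (strict
#'   inequality: an arc must last *more* than this).
#' @param min_fm_st Named numeric vector of minimum frequency-modulation
#'   amplitudes (semitones) per vocalization type: cry (`C`), early non-cry
#'   (`NC`), marginal (`BM`) and canonical (`BC`) babbling.
#' @param prominence_st Minimum prominence (semitones) for an extremum to seed
#'   an arc candidate; smaller wiggles are cancelled in flanking-pair order.
#' @param max_pause_ms Longest unvoiced gap accepted as a complete laryngeal
#'   constriction. Longer internal silences are flagged for review: a
#'   vocalization is one expiration, so long silence suggests an upstream
#'   segmentation error.
#' @param shape_r_low,shape_r_high Relative peak-position bounds separating
#'   left-accentuated (`r < shape_r_low`), symmetric and right-accentuated
#'   (`r > shape_r_high`) arc shapes, where `r = (t_peak - t_start)/duration`.
#' @param irregularity_factor Incomplete-constriction (creak) detector fires
#'   where the rolling median absolute *second* difference of the semitone
#'   track exceeds this multiple of the vocalization's overall median.
#' @param irregularity_floor_st Absolute floor (semitones) on the creak
#'   threshold, guarding against near-zero medians on very smooth contours;
#'   smooth melodies stay well below it (curvature per 5 ms step is a few
#'   hundredths of a semitone) while creak-like alternating jitter exceeds it
#'   by an order of magnitude.
#' @param creak_min_ms Minimum duration of an irregular stretch to count as an
#'   incomplete constriction.
#' @param max_jump_st Sample-to-sample semitone step beyond which a contour is
#'   flagged as no-pattern (sudden f0 shift, e.g. an octave tracking jump).
#'
#' @return A named list of class `melody_config`.
#' @seealso [read_melody_config()], [write_melody_config()]
#' @export
#' @examples
#' cfg <- melody_config()
#' cfg$min_fm_st[["C"]]
melody_config <- function(fs_hz = 200,
                          cutoff_hz = 40,
                          f_ref_hz = 440,
                          gap_bridge_ms = 20,
                          min_duration_s = 0.3,
                          min_fm_st = c(C = 2, NC = 1.5, BM = 1, BC = 1),
                          prominence_st = 0.25,
                          max_pause_ms = 250,
                          shape_r_low = 0.4,
                          shape_r_high = 0.6,
                          irregularity_factor = 5,
                          irregularity_floor_st = 0.5,
                          creak_min_ms = 50,
                          max_jump_st = 6) {
  if (fs_hz <= 2 * cutoff_hz) {
    stop("fs_hz must exceed twice cutoff_hz (need fs_hz > ", 2 * cutoff_hz,
         " Hz); resample at a higher rate", call. = FALSE)
  }
  stopifnot(f_ref_hz > 0, gap_bridge_ms >= 0, min_duration_s > 0,
            all(min_fm_st > 0), prominence_st > 0, max_pause_ms > 0,
            shape_r_low > 0, shape_r_high < 1, shape_r_low < shape_r_high)
  req <- c("C", "NC", "BM", "BC")
  if (!all(req %in% names(min_fm_st))) {
    stop("min_fm_st must name all vocalization types: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    fs_hz = fs_hz, cutoff_hz = cutoff_hz, f_ref_hz = f_ref_hz,
    gap_bridge_ms = gap_bridge_ms, min_duration_s = min_duration_s,
    min_fm_st = min_fm_st[req], prominence_st = prominence_st,
    max_pause_ms = max_pause_ms, shape_r_low = shape_r_low,
    shape_r_high = shape_r_high, irregularity_factor = irregularity_factor,
    irregularity_floor_st = irregularity_floor_st, creak_min_ms = creak_min_ms,
    max_jump_st = max_jump_st
  )
  class(cfg) <- "melody_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected rather than ignored, so a typo in a config file
#' cannot silently fall back to a default.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [melody_config()].
#' @return A `melody_config` list.
#' @export
read_melody_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(melody_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$min_fm_st)) raw$min_fm_st <- unlist(raw$min_fm_st)
  do.call(melody_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param config A `melody_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melody_config <- function(config, path) {
  x <- unclass(config)
  x$min_fm_st <- as.list(x$min_fm_st)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.melody_config <- function(x, ...) {
  cat("Melody analysis configuration\n")
  cat(sprintf("  grid: %g Hz, Gaussian low-pass cutoff %g Hz (-3 dB), f_ref %g Hz\n",
              x$fs_hz, x$cutoff_hz, x$f_ref_hz))
  cat(sprintf("  arcs: duration > %g s, min FM (st): %s\n", x$min_duration_s,
              paste(names(x$min_fm_st), x$min_fm_st, sep = "=", collapse = " ")))
  cat(sprintf("  segmentation: pause (%g, %g] ms, creak >= %g ms at %gx median irregularity\n",
              x$gap_bridge_ms, x$max_pause_ms, x$creak_min_ms,
              x$irregularity_factor))
  invisible(x)
}

# numerical slack for the printed duration bounds: 0.300 s built on a 5 ms grid
# is not exactly representable in binary, and the inclusive/strict senses of
# the two duration criteria must survive that.
.tol <- 1e-9

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
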