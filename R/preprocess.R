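#' Convert frequency to semitones
#'
#' The musical semitone scale is logarithmic in frequency: doubling `f` adds
#' exactly 12 semitones. Arc criteria are expressed in semitone differences,
#' so the reference frequency cancels there.
#'
#' @param f Frequency in Hz (> 0).
#' @param f_ref Reference frequency in Hz (> 0) mapped to 0 semitones.
#' @return Semitones relative to `f_ref`.
#' @export
#' @examples
#' hz_to_semitones(880, 440)  # one octave = 12
hz_to_semitones <- function(f, f_ref = 440) {
  if (any(f <= 0, na.rm = TRUE) || any(f_ref <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  12 * log2(f / f_ref)
}

#' @rdname hz_to_semitones
#' @param st Semitones relative to `f_ref`.
#' @export
semitones_to_hz <- function(st, f_ref = 440) f_ref * 2^(st / 12)

#' Quantize semitones to the quarter-tone grid
#'
#' Display/export helper: melody diagrams use a quarter-tone (0.5 semitone)
#' grid. Quantization is never applied inside the arc criteria — thresholding
#' quantized values would make the 1.0/1.5/2.0-semitone criteria
#' grid-dependent. Ties round away from zero.
#'
#' @param st Semitone values.
#' @return Nearest multiples of 0.5 semitones.
#' @export
#' @examples
#' quantize_quartertone(c(0.2, 0.25, -0.25))
quantize_quartertone <- function(st) {
  stopifnot(all(is.finite(st)))
  sign(st) * floor(abs(st) / 0.5 + 0.5) * 0.5
}

#' Resample a contour onto a uniform semitone grid
#'
#' Converts the voiced samples to semitones and interpolates them linearly on
#' a uniform grid at `fs_hz`. Interpolation happens within voiced runs only:
#' unvoiced dropouts up to `gap_bridge_ms` are bridged, longer gaps split the
#' contour into separate runs that are never mixed.
#'
#' @param contour An [f0_contour()] with at least two voiced samples.
#' @param config A [melody_config()] supplying `fs_hz`, `f_ref_hz` and
#'   `gap_bridge_ms`.
#' @return A `melody_track`: list with uniform `times`, semitone values `st`
#'   (`NA` outside voiced runs), integer run index matrix `runs`
#'   (columns `i_start`, `i_end`), sampling rate `fs`, reference `f_ref`,
#'   `source_id`, and `smoothed = FALSE`.
#' @export
resample_uniform <- function(contour, config = melody_config()) {
  voiced <- contour$voiced
  if (sum(voiced) < 2L) {
    stop("no voiced material in contour '", contour$vocalization_id,
         "' (need >= 2 voiced samples)", call. = FALSE)
  }
  fs <- config$fs_hz
  vt <- contour$times[voiced]
  vst <- hz_to_semitones(contour$f0_hz[voiced], config$f_ref_hz)
  spans <- voiced_run_spans(contour, config$gap_bridge_ms)

  t0 <- vt[1L]
  n_grid <- floor((vt[length(vt)] - t0) * fs + .tol) + 1L
  times <- t0 + (seq_len(n_grid) - 1L) / fs
  st <- rep(NA_real_, n_grid)
  runs <- matrix(integer(0), ncol = 2L,
                 dimnames = list(NULL, c("i_start", "i_end")))
  for (r in seq_len(nrow(spans))) {
    i0 <- as.integer(ceiling((spans[r, 1L] - t0) * fs - .tol)) + 1L
    i1 <- as.integer(floor((spans[r, 2L] - t0) * fs + .tol)) + 1L
    if (i1 < i0) next  # run shorter than one grid step
    sel <- vt >= spans[r, 1L] - .tol & vt <= spans[r, 2L] + .tol
    if (sum(sel) == 1L) {
      st[i0:i1] <- vst[sel]
    } else {
      st[i0:i1] <- stats::approx(vt[sel], vst[sel], xout = times[i0:i1],
                                 rule = 2)$y
    }
    runs <- rbind(runs, c(i0, i1))
  }
  if (nrow(runs) == 0L) {
    stop("no voiced material in contour '", contour$vocalization_id,
         "' after gridding", call. = FALSE)
  }
  structure(list(times = times, st = st, runs = runs, fs = fs,
                 f_ref = config$f_ref_hz, source_id = contour$vocalization_id,
                 smoothed = FALSE),
            class = "melody_track")
}

#' @export
print.melody_track <- function(x, ...) {
  cat(sprintf("melody track '%s': %d samples @ %g Hz, %d voiced run(s)%s\n",
              x$source_id, length(x$times), x$fs, nrow(x$runs),
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Voiced run intervals of a melody track
#'
#' @param track A `melody_track`.
#' @return Matrix with columns `t_start`, `t_end` in seconds.
#' @export
voiced_runs <- function(track) {
  cbind(t_start = track$times[track$runs[, 1L]],
        t_end = track$times[track$runs[, 2L]])
}

#' Gaussian low-pass filter of a melody track
#'
#' Smooths the semitone contour with a Gaussian filter whose -3 dB point is
#' `cutoff_hz`: in the frequency domain the gain is
#' `exp(-f^2 / (2 * sigma_f^2))` with `sigma_f = cutoff_hz / sqrt(ln 2)`
#' (equivalently a Gaussian kernel of width `sigma_t = 1/(2 pi sigma_f)` in
#' time). The filter removes high-frequency modulation noise and artifacts
#' before arc decomposition. Each voiced run is filtered independently with
#' reflected edges, so run boundaries never mix.
#'
#' @param track A uniform `melody_track` from [resample_uniform()].
#' @param config A [melody_config()] supplying `cutoff_hz`.
#' @return The track with smoothed `st` and `smoothed = TRUE`.
#' @export
gaussian_lowpass <- function(track, config = melody_config()) {
  cutoff <- config$cutoff_hz
  fs <- track$fs
  if (fs <= 2 * cutoff) {
    stop("sampling rate ", fs, " Hz too low for a ", cutoff,
         " Hz cutoff; resample at fs > ", 2 * cutoff, " Hz", call. = FALSE)
  }
  sigma_f <- cutoff / sqrt(log(2))
  st <- track$st
  for (r in seq_len(nrow(track$runs))) {
    i0 <- track$runs[r, 1L]; i1 <- track$runs[r, 2L]
    st[i0:i1] <- .gauss_smooth_run(st[i0:i1], fs, sigma_f)
  }
  track$st <- st
  track$smoothed <- TRUE
  track
}

# frequency-domain Gaussian smoothing of one run with reflection padding
.gauss_smooth_run <- function(y, fs, sigma_f) {
  n <- length(y)
  if (n < 3L) return(y)
  pad <- min(n - 1L, 32L)
  yp <- c(y[(pad + 1L):2L], y, y[(n - 1L):(n - pad)])
  m <- length(yp)
  f <- (seq_len(m) - 1L) * fs / m
  f <- pmin(f, fs - f)          # two-sided frequency axis
  gain <- exp(-f^2 / (2 * sigma_f^2))
  ys <- Re(stats::fft(stats::fft(yp) * gain, inverse = TRUE)) / m
  ys[(pad + 1L):(pad + n)]
}

#' Theoretical gain of the Gaussian low-pass
#'
#' Closed-form transfer function used by the filter: handy for picking a
#' cutoff or checking attenuation at a given modulation frequency.
#'
#' @param f Modulation frequency in Hz.
#' @param cutoff_hz -3 dB cutoff in Hz.
#' @return Linear gain in (0, 1].
#' @export
gaussian_gain <- function(f, cutoff_hz = 40) {
  sigma_f <- cutoff_hz / sqrt(log(2))
  exp(-f^2 / (2 * sigma_f^2))
}

#' Preprocess a contour: semitone scale, uniform grid, Gaussian smoothing
#'
#' Convenience wrapper chaining [resample_uniform()] and [gaussian_lowpass()].
#'
#' @inheritParams resample_uniform
#' @return A smoothed `melody_track`.
#' @export
preprocess_contour <- function(contour, config = melody_config()) {
  gaussian_lowpass(resample_uniform(contour, config), config)
}
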