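#' Inclusion filter for melody pattern analysis
#'
#' A vocalization enters melody analysis only if its melody can unfold and be
#' tracked reliably. Two exclusion reasons exist: `too_short` — total voiced
#' duration of at most 300 ms (inclusive bound; the melody cannot unfold in
#' the short time available) — and `no_pattern` — a manual flag, or an
#' automatic instability flag for sudden f0 shifts (sample-to-sample steps
#' beyond `max_jump_st`, e.g. octave tracking jumps).
#'
#' @param contour An [f0_contour()].
#' @param config A [melody_config()].
#' @return A list with `included` (logical) and `reason` (`"none"`,
#'   `"too_short"` or `"no_pattern"`).
#' @export
apply_inclusion_filter <- function(contour, config = melody_config()) {
  vd <- voiced_duration(contour, config$gap_bridge_ms)
  if (vd <= config$min_duration_s + .tol) {
    return(list(included = FALSE, reason = "too_short"))
  }
  if (isTRUE(contour$manual_no_pattern) || .has_f0_jump(contour, config)) {
    return(list(included = FALSE, reason = "no_pattern"))
  }
  list(included = TRUE, reason = "none")
}

# sudden-f0-shift flag: a semitone step beyond max_jump_st between consecutive
# voiced samples of the same run (steps across unvoiced gaps carry no
# continuity expectation and are ignored)
.has_f0_jump <- function(contour, config) {
  vi <- contour$voiced
  if (sum(vi) < 2L) return(FALSE)
  vt <- contour$times[vi]
  vst <- hz_to_semitones(contour$f0_hz[vi], config$f_ref_hz)
  dt <- diff(vt)
  med <- stats::median(dt)
  within <- !(dt > 1.5 * med & (dt - med) > config$gap_bridge_ms / 1000 + .tol)
  any(abs(diff(vst))[within] > config$max_jump_st)
}

#' Locate melody extrema per voiced run
#'
#' Returns, for every voiced run of a smoothed track, a strictly alternating
#' sequence of minima and maxima that starts and ends at the run boundary
#' points. Plateaus of equal values collapse to their midpoint. Extremum pairs
#' whose amplitude difference falls below the prominence floor are cancelled
#' (smallest pair first) before arc building, so residual grid noise cannot
#' seed arc candidates.
#'
#' @param track A smoothed `melody_track` (see [gaussian_lowpass()]).
#' @param config A [melody_config()] supplying `prominence_st`.
#' @return A data frame with columns `run`, `idx` (grid index), `t` (seconds),
#'   `value` (semitones; merged extrema may adopt the more extreme value of
#'   the pair they absorbed), `type` (`"min"`/`"max"`).
#' @export
find_extrema <- function(track, config = melody_config()) {
  out <- vector("list", nrow(track$runs))
  for (r in seq_len(nrow(track$runs))) {
    i0 <- track$runs[r, 1L]; i1 <- track$runs[r, 2L]
    ext <- .run_extrema(track$st[i0:i1], config$prominence_st)
    if (nrow(ext)) {
      ext$idx <- ext$idx + i0 - 1L
      ext$t <- track$times[ext$idx]
      ext$run <- r
    }
    out[[r]] <- ext
  }
  res <- do.call(rbind, out)
  res[, c("run", "idx", "t", "value", "type")]
}

# alternating extrema of one run, pruned at the prominence floor
.run_extrema <- function(y, prom) {
  n <- length(y)
  if (n == 1L) {
    return(data.frame(idx = 1L, value = y, type = "min"))
  }
  # collapse plateaus of (numerically) equal consecutive values to midpoints
  new_grp <- c(TRUE, abs(diff(y)) > 1e-12)
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  last <- c(first[-1L] - 1L, n)
  idx2 <- as.integer(ceiling((first + last) / 2))
  y2 <- y[first]
  m <- length(idx2)
  if (m == 1L) {  # constant run
    return(data.frame(idx = c(1L, n), value = y[c(1L, n)],
                      type = c("min", "max")))
  }
  s <- sign(diff(y2))
  turn <- if (m > 2L) which(s[-1L] != s[-(m - 1L)]) + 1L else integer(0)
  t_type <- ifelse(s[turn - 1L] > 0, "max", "min")
  first_type <- if (length(turn)) {
    if (t_type[1L] == "max") "min" else "max"
  } else if (s[1L] > 0) "min" else "max"
  last_type <- if (length(turn)) {
    if (t_type[length(t_type)] == "max") "min" else "max"
  } else if (first_type == "min") "max" else "min"
  ext <- data.frame(
    idx = idx2[c(1L, turn, m)],
    value = y2[c(1L, turn, m)],
    type = c(first_type, t_type, last_type)
  )
  ext$idx[1L] <- 1L
  ext$idx[nrow(ext)] <- n
  ext$value[1L] <- y[1L]
  ext$value[nrow(ext)] <- y[n]
  .prune_extrema(ext, prom)
}

# cancel sub-prominence extremum pairs, smallest first. An interior pair is
# deleted outright; a pair touching a run boundary is a noise wiggle at the
# run's edge, so its interior member is deleted and the boundary anchor takes
# over that member's min/max role (keeping the anchor's own time and value),
# which preserves alternation with the rest of the sequence.
.prune_extrema <- function(ext, prom) {
  repeat {
    k <- nrow(ext)
    if (k <= 2L) break
    amps <- abs(diff(ext$value))
    m <- which.min(amps)
    if (amps[m] >= prom) break
    if (m > 1L && m + 1L < k) {               # pair fully interior
      ext <- ext[-c(m, m + 1L), ]
    } else if (m == 1L) {                     # pair includes left boundary
      ext$type[1L] <- ext$type[2L]
      ext <- ext[-2L, ]
    } else {                                  # pair includes right boundary
      ext$type[k] <- ext$type[k - 1L]
      ext <- ext[-(k - 1L), ]
    }
  }
  rownames(ext) <- NULL
  ext
}

#' Arc acceptance criteria
#'
#' A melody arc must last more than `min_duration_s` (strict) and modulate f0
#' by at least the vocalization-type-specific minimum FM amplitude: 2
#' semitones for cry, 1.5 for early non-cry, 1 for marginal and canonical
#' babbling. FM amplitude is measured from the arc peak down to the *higher*
#' of its two flanking minima, so both the rise and the fall reach the
#' criterion.
#'
#' @param min_duration_s Minimum arc duration (seconds, strict bound).
#' @param min_fm_st Named minimum FM amplitudes per vocalization type.
#' @return A list of class `arc_criteria`.
#' @export
arc_criteria <- function(min_duration_s = 0.3,
                         min_fm_st = c(C = 2, NC = 1.5, BM = 1, BC = 1)) {
  structure(list(min_duration_s = min_duration_s, min_fm_st = min_fm_st),
            class = "arc_criteria")
}

#' Decompose a smoothed melody into arcs
#'
#' Arc candidates are min-max-min triplets of the pruned extremum sequence of
#' each voiced run. A candidate failing a criterion is merged into the
#' neighbouring arc that shares its higher flanking minimum: the failing peak
#' and that shared minimum — the adjacent extremum pair whose amplitude the
#' failed FM criterion bounds — are cancelled, smallest pair first for the FM
#' criterion (ties merge right) and one candidate at a time for the duration
#' criterion, and candidates are recomputed, iterating to a fixpoint. A run
#' longer than the minimum duration whose total range stays below the FM
#' criterion yields a single plateau arc (the flat-melody prototype).
#'
#' @param track A smoothed `melody_track`.
#' @param voc_type Vocalization type selecting the FM criterion.
#' @param config A [melody_config()].
#' @return A data frame of accepted arcs: `t_start`, `t_peak`, `t_end`,
#'   `duration`, `fm_st`, `shape`.
#' @export
extract_arcs <- function(track, voc_type = c("C", "NC", "BM", "BC"),
                         config = melody_config()) {
  voc_type <- match.arg(voc_type)
  min_fm <- config$min_fm_st[[voc_type]]
  min_dur <- config$min_duration_s
  out <- vector("list", nrow(track$runs))
  for (r in seq_len(nrow(track$runs))) {
    i0 <- track$runs[r, 1L]; i1 <- track$runs[r, 2L]
    y <- track$st[i0:i1]
    tt <- track$times[i0:i1]
    ext <- .run_extrema(y, config$prominence_st)
    arcs <- .extract_run_arcs(ext, tt, min_dur, min_fm, config)
    if (is.null(arcs) || nrow(arcs) == 0L) {
      run_dur <- tt[length(tt)] - tt[1L]
      rng <- max(y) - min(y)
      if (run_dur > min_dur + .tol && rng < min_fm - .tol) {
        arcs <- data.frame(t_start = tt[1L], t_peak = tt[ceiling(length(tt) / 2)],
                           t_end = tt[length(tt)], duration = run_dur,
                           fm_st = rng, shape = "plateau")
      } else {
        arcs <- NULL
      }
    }
    out[[r]] <- arcs
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(t_start = numeric(0), t_peak = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      fm_st = numeric(0), shape = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Merge-to-fixpoint arc acceptance on one run's extremum sequence. The FM
# criterion (peak at least min_fm above its higher flanking minimum) is
# equivalent to every adjacent extremum pair spanning at least min_fm, so
# sub-threshold candidates are merged by smallest-pair-first cancellation —
# the same total-variation reduction as the prominence pruning, at the FM
# threshold. Small ripples therefore vanish before they can cost a true peak
# its summit. Duration failures are then merged one at a time (cancelling the
# failing peak with its higher flanking minimum) and the FM pruning re-run.
.extract_run_arcs <- function(ext, tt, min_dur, min_fm, config) {
  repeat {
    ext <- .prune_extrema(ext, min_fm - .tol)
    k <- nrow(ext)
    cand <- which(ext$type == "max")
    cand <- cand[cand > 1L & cand < k]
    if (!length(cand)) return(NULL)
    fail <- 0L
    for (i in cand) {
      dur <- tt[ext$idx[i + 1L]] - tt[ext$idx[i - 1L]]
      if (!(dur > min_dur + .tol)) { fail <- i; break }
    }
    if (!fail) break
    ext <- .merge_failed_arc(ext, fail)
  }
  do.call(rbind, lapply(cand, function(i) {
    ts <- tt[ext$idx[i - 1L]]; tp <- tt[ext$idx[i]]; te <- tt[ext$idx[i + 1L]]
    data.frame(t_start = ts, t_peak = tp, t_end = te, duration = te - ts,
               fm_st = ext$value[i] - max(ext$value[i - 1L], ext$value[i + 1L]),
               shape = classify_arc_shape(ts, tp, te, config))
  }))
}

# Remove the failing candidate peak at position i by merging it into the
# neighbour that shares its *higher* flanking minimum (ties merge right).
# The failing condition fm = peak - max(flanks) < threshold says precisely
# that (peak, higher flank) is the low-amplitude pair, so cancelling that
# pair removes the sub-threshold modulation while leaving the deeper minimum
# -- typically the true junction between arcs -- in place. Cancelling the
# lower flank instead would let each noise ripple consume a real junction
# minimum and cascade neighbouring arcs into one. When the higher flank is a
# run boundary anchor, the anchor survives and takes over the peak's role.
.merge_failed_arc <- function(ext, i) {
  k <- nrow(ext)
  vl <- ext$value[i - 1L]; vr <- ext$value[i + 1L]
  if (vl > vr) {                    # higher flank on the left
    if (i - 1L == 1L) {
      ext$type[1L] <- ext$type[i]
      ext <- ext[-i, ]
    } else {
      ext <- ext[-c(i - 1L, i), ]
    }
  } else {                          # higher flank on the right (ties right)
    if (i + 1L == k) {
      ext$type[k] <- ext$type[i]
      ext <- ext[-i, ]
    } else {
      ext <- ext[-c(i, i + 1L), ]
    }
  }
  rownames(ext) <- NULL
  ext
}

#' Classify the shape prototype of an arc
#'
#' Four shape prototypes are distinguished by the relative peak position
#' `r = (t_peak - t_start)/duration`: a fast rise with slow fall
#' (`r < shape_r_low`) is left-accentuated, a slow rise with fast fall
#' (`r > shape_r_high`) right-accentuated, otherwise symmetric. Flat runs
#' below the FM criterion are the fourth, plateau prototype (assigned in
#' [extract_arcs()], not here).
#'
#' @param t_start,t_peak,t_end Arc landmark times in seconds.
#' @param config A [melody_config()] supplying the `r` thresholds.
#' @return `"left_accentuated"`, `"symmetric"` or `"right_accentuated"`.
#' @export
classify_arc_shape <- function(t_start, t_peak, t_end,
                               config = melody_config()) {
  r <- (t_peak - t_start) / (t_end - t_start)
  if (r < config$shape_r_low) "left_accentuated"
  else if (r > config$shape_r_high) "right_accentuated"
  else "symmetric"
}

#' Detect intra-melodic segmentation events
#'
#' Segmentation events are breaks in the melody caused by laryngeal
#' constrictions. A *complete* constriction interrupts phonation and shows as
#' an internal unvoiced gap longer than the bridge length and up to
#' `max_pause_ms`; longer internal silences are flagged for review rather
#' than counted (a single-expiration vocalization cannot contain long
#' silence, so these suggest an upstream segmentation error). An *incomplete*
#' constriction leaves phonation running but irregular (creak/straw-bass):
#' it is detected as a stretch of at least `creak_min_ms` whose rolling median
#' absolute second difference of the semitone track — computed on the raw,
#' pre-smoothing samples, so smooth-but-steep melody slopes do not register —
#' exceeds `irregularity_factor` times the vocalization's median (with an
#' absolute floor). The creak detector is a declared proxy for the
#' audio-visual identification used with real recordings; the manual
#' no-pattern channel can override it in either direction.
#'
#' @param track A `melody_track` (for voiced-run boundaries).
#' @param contour The raw [f0_contour()] (for the pre-smoothing irregularity
#'   score).
#' @param config A [melody_config()].
#' @return A data frame with columns `t` (event midpoint, seconds), `kind`
#'   (`"complete"`/`"incomplete"`) and `gap_duration_s` (`NA` for incomplete
#'   events), carrying attribute `truncation_gaps` with any over-long gaps.
#' @export
detect_segmentation_events <- function(track, contour,
                                       config = melody_config()) {
  events <- list()
  truncation <- numeric(0)
  vr <- voiced_runs(track)
  if (nrow(vr) > 1L) {
    for (kk in seq_len(nrow(vr) - 1L)) {
      gap <- vr[kk + 1L, 1L] - vr[kk, 2L]
      if (gap <= config$max_pause_ms / 1000 + .tol) {
        events[[length(events) + 1L]] <-
          data.frame(t = unname((vr[kk, 2L] + vr[kk + 1L, 1L]) / 2),
                     kind = "complete", gap_duration_s = unname(gap))
      } else {
        truncation <- c(truncation, unname(gap))
      }
    }
  }
  irr <- .creak_intervals(contour, config)
  for (jj in seq_len(nrow(irr))) {
    events[[length(events) + 1L]] <-
      data.frame(t = (irr[jj, 1L] + irr[jj, 2L]) / 2,
                 kind = "incomplete", gap_duration_s = NA_real_)
  }
  res <- if (length(events)) do.call(rbind, events) else {
    data.frame(t = numeric(0), kind = character(0),
               gap_duration_s = numeric(0))
  }
  res <- res[order(res$t), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "truncation_gaps") <- truncation
  res
}

# Intervals (t_start, t_end) of sustained f0 irregularity on the raw
# (pre-smoothing) samples. The score is the absolute *second* difference of
# the semitone track: near zero for any smooth melody regardless of slope
# (a steep but clean arc has small curvature per 5 ms step), but on the order
# of several semitones for creak-like alternating jitter, so the two separate
# cleanly. A stretch counts when its rolling median exceeds
# irregularity_factor times the vocalization's median (with an absolute
# floor) for at least creak_min_ms.
.creak_intervals <- function(contour, config) {
  vi <- contour$voiced
  none <- matrix(numeric(0), ncol = 2L)
  if (sum(vi) < 5L) return(none)
  vt <- contour$times[vi]
  vst <- hz_to_semitones(contour$f0_hz[vi], config$f_ref_hz)
  n <- length(vt)
  dt <- diff(vt)
  med_dt <- stats::median(dt)
  split <- dt > 1.5 * med_dt & (dt - med_dt) > config$gap_bridge_ms / 1000 + .tol
  run_id <- cumsum(c(1L, as.integer(split)))  # run id per sample
  d2 <- abs(diff(vst, differences = 2L))      # d2[j] spans samples j..j+2
  same_run <- run_id[1:(n - 2L)] == run_id[3:n]
  if (!any(same_run)) return(none)
  thr <- max(config$irregularity_factor * stats::median(d2[same_run]),
             config$irregularity_floor_st)
  k_w <- max(3L, round(0.05 / med_dt))
  if (k_w %% 2L == 0L) k_w <- k_w + 1L
  out <- list()
  for (rid in unique(run_id)) {
    sel <- which(same_run & run_id[seq_len(n - 2L)] == rid)
    if (length(sel) < 3L) next
    k <- min(k_w, length(sel) - (1 - length(sel) %% 2L))
    score <- stats::runmed(d2[sel], k, endrule = "median")
    marked <- score > thr
    if (!any(marked)) next
    mr <- rle(marked)
    ends <- cumsum(mr$lengths)
    starts <- ends - mr$lengths + 1L
    for (b in which(mr$values)) {
      t0 <- vt[sel[starts[b]] + 1L]   # centre sample of the triple
      t1 <- vt[sel[ends[b]] + 1L]
      if (t1 - t0 >= config$creak_min_ms / 1000 - 2 * med_dt) {
        out[[length(out) + 1L]] <- c(t0, t1)
      }
    }
  }
  if (!length(out)) return(none)
  do.call(rbind, out)
}

#' Classify a vocalization's melody category
#'
#' Combines arc and segmentation evidence into the final verdict. Excluded
#' vocalizations get category `excluded`. A melody with at least one
#' segmentation event is `SEG`, *independent of arc numbers*. Otherwise the
#' arc count decides: 1 arc `SA`, 2 `DA`, 3 `TA`, 4 or more `MA`. A run
#' surviving only as a plateau counts as its single arc (`SA`). Complexity is
#' 0 for `SA` and 1 for every complex category.
#'
#' @param arcs Arc table from [extract_arcs()].
#' @param events Event table from [detect_segmentation_events()].
#' @param included,reason Inclusion verdict from [apply_inclusion_filter()].
#' @return A list with `included`, `exclusion_reason`, `n_arcs`,
#'   `n_segmentations`, `category` and `complexity`.
#' @export
classify_melody <- function(arcs, events, included = TRUE, reason = "none") {
  if (!included) {
    return(list(included = FALSE, exclusion_reason = reason, n_arcs = 0L,
                n_segmentations = 0L, category = "excluded",
                complexity = NA_integer_))
  }
  n_arcs <- if (is.null(arcs)) 0L else nrow(arcs)
  n_seg <- if (is.null(events)) 0L else nrow(events)
  category <- if (n_seg >= 1L) "SEG"
              else if (n_arcs >= 4L) "MA"
              else if (n_arcs == 3L) "TA"
              else if (n_arcs == 2L) "DA"
              else "SA"
  list(included = TRUE, exclusion_reason = "none", n_arcs = n_arcs,
       n_segmentations = n_seg, category = category,
       complexity = if (category == "SA") 0L else 1L)
}
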