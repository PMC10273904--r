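#' Synthetic-contour noise and shape parameters
#'
#' Defaults emulate realistic infant f0 tracks: per-sample tracker jitter,
#' vocal tremor above the smoothing cutoff (so the low-pass filter's purpose
#' is exercised), arc durations and per-type FM-amplitude and register ranges.
#' Per-category FM and duration distributions of real corpora are unpublished;
#' these ranges are declared assumptions of the generator.
#'
#' @param fs_hz Sampling rate of generated tracks, in Hz.
#' @param jitter_st Per-sample Gaussian jitter s.d., semitones.
#' @param tremor_hz,tremor_depth_st Sinusoidal tremor frequency (Hz) and
#'   amplitude (semitones); the default 70 Hz lies above the 40 Hz cutoff.
#' @param arc_duration_range Arc duration range, seconds.
#' @param fm_range_st Named list of per-type FM amplitude ranges (semitones).
#' @param base_f0_range_hz Named list of per-type baseline f0 ranges (Hz).
#' @param pause_range_s Complete-constriction gap duration range, seconds.
#' @param creak_range_s Incomplete-constriction (creak) duration range,
#'   seconds.
#' @param creak_depth_st Creak alternating-sample amplitude, semitones.
#' @return A named list of class `synth_params`.
#' @export
synth_params <- function(fs_hz = 200,
                         jitter_st = 0.1,
                         tremor_hz = 70,
                         tremor_depth_st = 0.3,
                         arc_duration_range = c(0.35, 1.2),
                         fm_range_st = list(C = c(2, 8), NC = c(1.5, 6),
                                            BM = c(1, 5), BC = c(1, 5)),
                         base_f0_range_hz = list(C = c(350, 500),
                                                 NC = c(300, 450),
                                                 BM = c(250, 400),
                                                 BC = c(250, 400)),
                         pause_range_s = c(0.04, 0.2),
                         creak_range_s = c(0.06, 0.1),
                         creak_depth_st = 1.5) {
  structure(list(fs_hz = fs_hz, jitter_st = jitter_st, tremor_hz = tremor_hz,
                 tremor_depth_st = tremor_depth_st,
                 arc_duration_range = arc_duration_range,
                 fm_range_st = fm_range_st,
                 base_f0_range_hz = base_f0_range_hz,
                 pause_range_s = pause_range_s, creak_range_s = creak_range_s,
                 creak_depth_st = creak_depth_st),
            class = "synth_params")
}

# corpus of the reference study design: included vocalizations analysed per
# infant per month (10 infants, months 1-12; grand total 9,237)
.default_counts <- function() {
  m <- rbind(
    c(47,   7,  92,  71, 199,  44,  25,   0,  37,   2,   0,   0),
    c(84, 103, 112, 198,  11,  18,  12,   0,  21,  16,   0,   0),
    c(79,  82, 151, 138,  21,  94,  74,  15,  20,  26,  22,   0),
    c(8,  134, 158, 141, 200,  99,   0,   0,   0,  54, 123,   0),
    c(81,  87, 105, 124, 104,  85,   0,  81,  60,  76, 136,   0),
    c(104, 200, 295, 266, 149, 127,  54,  40,  74,  92,  56,  0),
    c(0,  149,   0,   0,  68, 150,  68,  97, 152, 122,  72,   0),
    c(49, 267,  24,   0,   0,   0,   0,  10, 141,  30, 168,  37),
    c(64, 139,   0,   0, 196,  35,  40, 121, 141, 163,  33, 153),
    c(144, 148,  0,   0, 133, 224,  93, 174, 120,  56, 199, 123)
  )
  dimnames(m) <- list(sprintf("inf%02d", 1:10), sprintf("m%02d", 1:12))
  storage.mode(m) <- "integer"
  m
}

.default_sex <- function() {
  stats::setNames(c("male", "female", "female", "female", "female", "male",
                    "female", "male", "female", "male"),
                  sprintf("inf%02d", 1:10))
}

#' Corpus composition for the synthetic generator
#'
#' Defines everything [generate_corpus()] needs: the per-infant-per-month
#' counts of included vocalizations, the ground-truth category mixture, the
#' number of additional excluded records and their split between exclusion
#' reasons, the vocalization-type ratios within each age stratum, noise
#' parameters and the seed. The defaults reproduce the reference corpus
#' design: 9,237 included vocalizations (Table-1-style per-infant counts)
#' plus 1,751 excluded, a 39/21/7/3/30 SA/DA/TA/MA/SEG mixture, cry:non-cry
#' 1,141:4,667 in months 1--6 and marginal:canonical babbling 2,754:675 in
#' months 7--12.
#'
#' @param seed Integer seed; all generation is a pure function of
#'   (composition, seed).
#' @param counts Integer matrix (infants x months 1..12) of included
#'   vocalizations per cell.
#' @param sex Named character vector of infant sexes.
#' @param mixture Ground-truth category probabilities, summing to 1.
#' @param n_excluded Number of excluded records appended to the corpus.
#' @param too_short_frac Fraction of excluded records planted as `too_short`
#'   (the rest are `no_pattern`).
#' @param type_ratio_early Relative counts of `C`:`NC` in months 1--6.
#' @param type_ratio_late Relative counts of `BM`:`BC` in months 7--12.
#' @param params A [synth_params()] list.
#' @return A list of class `corpus_composition`.
#' @export
corpus_composition <- function(seed = 1L,
                               counts = .default_counts(),
                               sex = .default_sex(),
                               mixture = c(SA = 0.39, DA = 0.21, TA = 0.07,
                                           MA = 0.03, SEG = 0.30),
                               n_excluded = 1751L,
                               too_short_frac = 0.5,
                               type_ratio_early = c(C = 1141, NC = 4667),
                               type_ratio_late = c(BM = 2754, BC = 675),
                               params = synth_params()) {
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop("category mixture must sum to 1", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!setequal(names(mixture), c("SA", "DA", "TA", "MA", "SEG"))) {
    stop("mixture must name SA, DA, TA, MA, SEG", call. = FALSE)
  }
  if (!identical(sort(rownames(counts)), sort(names(sex)))) {
    stop("rownames(counts) must match names(sex)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), counts = counts, sex = sex,
                 mixture = mixture[c("SA", "DA", "TA", "MA", "SEG")],
                 n_excluded = as.integer(n_excluded),
                 too_short_frac = too_short_frac,
                 type_ratio_early = type_ratio_early,
                 type_ratio_late = type_ratio_late, params = params),
            class = "corpus_composition")
}

#' Path of the packaged default composition fixture
#'
#' @return Path to the YAML file shipped in `extdata`.
#' @export
default_composition_path <- function() {
  system.file("extdata", "default_composition.yaml", package = "melodyarc",
              mustWork = TRUE)
}

#' Read a corpus composition from YAML
#'
#' @param path Path to a composition YAML file (see the packaged fixture at
#'   [default_composition_path()]).
#' @param seed Seed overriding the file's `seed` entry, if given.
#' @return A `corpus_composition`.
#' @export
read_composition <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  counts <- do.call(rbind, lapply(raw$counts, as.integer))
  rownames(counts) <- names(raw$counts)
  colnames(counts) <- sprintf("m%02d", seq_len(ncol(counts)))
  params <- if (is.null(raw$params)) synth_params() else {
    pr <- raw$params
    for (k in c("fm_range_st", "base_f0_range_hz")) {
      if (!is.null(pr[[k]])) pr[[k]] <- lapply(pr[[k]], as.numeric)
    }
    for (k in c("arc_duration_range", "pause_range_s", "creak_range_s")) {
      if (!is.null(pr[[k]])) pr[[k]] <- as.numeric(pr[[k]])
    }
    do.call(synth_params, pr)
  }
  corpus_composition(
    seed = if (!is.null(seed)) seed else raw$seed,
    counts = counts,
    sex = unlist(raw$sex),
    mixture = unlist(raw$mixture),
    n_excluded = raw$n_excluded,
    too_short_frac = raw$too_short_frac,
    type_ratio_early = unlist(raw$type_ratio_early),
    type_ratio_late = unlist(raw$type_ratio_late),
    params = params
  )
}

#' Largest-remainder apportionment
#'
#' Splits `n` items over categories proportionally to `probs`, rounding by
#' the largest-remainder rule: floors first, then one extra item per category
#' in decreasing order of fractional remainder (ties by category order). The
#' result is deterministic — seed-free — so configured shares are met up to
#' integer rounding.
#'
#' @param n Total count.
#' @param probs Non-negative weights (normalised internally).
#' @return Integer vector summing to `n`, same names as `probs`.
#' @export
apportion_largest_remainder <- function(n, probs) {
  p <- probs / sum(probs)
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

#' Generate one melody arc
#'
#' Builds a smooth rise-then-fall f0 segment from one of the four shape
#' prototypes as a piecewise raised cosine with the peak at 25%, 50% or 75%
#' of the duration for left-accentuated, symmetric and right-accentuated
#' shapes. The plateau prototype is a flat contour with a small linear drift
#' (range below half a semitone). Deterministic given its arguments.
#'
#' @param shape `"left_accentuated"`, `"symmetric"`, `"right_accentuated"` or
#'   `"plateau"`.
#' @param duration_s Arc duration in seconds.
#' @param f_start_hz Baseline f0 at the arc end points, Hz.
#' @param fm_st Frequency-modulation amplitude in semitones (peak over
#'   baseline); ignored for the plateau shape.
#' @param fs Sampling rate, Hz.
#' @return A list with `times` (seconds, from 0) and `f0_hz`.
#' @export
generate_arc <- function(shape, duration_s, f_start_hz, fm_st, fs = 200) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  st <- .arc_st(shape, fm_st, round(duration_s * fs) + 1L)
  times <- (seq_along(st) - 1L) / fs
  list(times = times, f0_hz = f_start_hz * 2^(st / 12))
}

# semitone curve of one arc; the plateau prototype is flat by definition and
# ignores the FM amplitude
.arc_st <- function(shape, fm_st, n) {
  prof <- arc_shape_profile(shape, n)
  if (shape == "plateau") prof else fm_st * prof
}

# unit-amplitude shape profile over n samples (0 at both ends except plateau)
arc_shape_profile <- function(shape, n) {
  x <- seq(0, 1, length.out = n)
  q <- switch(shape,
              left_accentuated = 0.25,
              symmetric = 0.5,
              right_accentuated = 0.75,
              plateau = return(0.3 * x),  # linear drift, range 0.3 st
              stop("invalid shape name '", shape, "'", call. = FALSE))
  ifelse(x <= q,
         0.5 * (1 - cos(pi * x / q)),
         0.5 * (1 + cos(pi * (x - q) / (1 - q))))
}

#' Generate one synthetic vocalization
#'
#' Renders a ground-truth label into an f0 contour: `true_n_arcs` arcs with
#' shapes sampled from the prototypes (the plateau prototype only for
#' single-arc melodies, where it represents the flat-melody type), per-arc FM
#' amplitudes from the vocalization type's range, complete segmentation
#' pauses (unvoiced gaps) and incomplete ones (planted creak irregularity) at
#' arc junctions, plus tremor and jitter noise. Planted `too_short` labels
#' yield a sub-300 ms contour; planted `no_pattern` labels carry a downward
#' octave jump (a classic tracking artifact) that trips the sudden-shift
#' flag. Fully reproducible from `label$seed`.
#'
#' @param label A one-row data frame or list with `vocalization_id`,
#'   `infant_id`, `sex`, `age_days`, `voc_type`, `true_category`,
#'   `true_n_arcs`, `true_n_segmentations`, `planted_exclusion` and `seed`.
#' @param params A [synth_params()] list.
#' @param noise Set `FALSE` to render the noise-free version of the same
#'   contour (same seed, no jitter/tremor).
#' @return An [f0_contour()].
#' @export
generate_vocalization <- function(label, params = synth_params(),
                                  noise = TRUE) {
  label <- as.list(label)
  with_seed(label$seed, .render_vocalization(label, params, noise))
}

.render_vocalization <- function(label, params, noise) {
  fs <- params$fs_hz
  vt <- label$voc_type
  base <- stats::runif(1, params$base_f0_range_hz[[vt]][1],
                       params$base_f0_range_hz[[vt]][2])
  fmr <- params$fm_range_st[[vt]]

  if (identical(label$planted_exclusion, "too_short")) {
    dur <- stats::runif(1, 0.15, 0.28)
    n <- round(dur * fs) + 1L
    st <- stats::runif(1, 1, 3) * arc_shape_profile("symmetric", n)
    times <- (seq_len(n) - 1L) / fs
    st <- .add_noise(st, times, params, noise)
    return(.label_contour(label, times, base * 2^(st / 12)))
  }

  n_arcs <- if (identical(label$planted_exclusion, "no_pattern")) 2L
            else label$true_n_arcs
  shapes <- if (n_arcs == 1L) {
    sample(c("left_accentuated", "symmetric", "right_accentuated", "plateau"), 1L)
  } else {
    sample(c("left_accentuated", "symmetric", "right_accentuated"), n_arcs,
           replace = TRUE)
  }
  durs <- stats::runif(n_arcs, params$arc_duration_range[1],
                       params$arc_duration_range[2])
  fms <- stats::runif(n_arcs, fmr[1], fmr[2])

  # segmentation plan: events sit at distinct arc junctions
  n_seg <- if (identical(label$planted_exclusion, "none"))
    label$true_n_segmentations else 0L
  seg_j <- if (n_seg > 0L) sort(sample(n_arcs - 1L, n_seg)) else integer(0)
  seg_kind <- sample(c("complete", "incomplete"), n_seg, replace = TRUE)

  times <- numeric(0)
  st <- numeric(0)
  cursor <- 0
  creaks <- list()
  for (k in seq_len(n_arcs)) {
    n_k <- round(durs[k] * fs) + 1L
    tt <- cursor + (seq_len(n_k) - 1L) / fs
    ss <- .arc_st(shapes[k], fms[k], n_k)
    if (k > 1L) { tt <- tt[-1L]; ss <- ss[-1L] }  # shared junction sample
    times <- c(times, tt)
    st <- c(st, ss)
    cursor <- tt[length(tt)]
    jpos <- match(k, seg_j)
    if (!is.na(jpos)) {
      if (seg_kind[jpos] == "complete") {
        cursor <- cursor + stats::runif(1, params$pause_range_s[1],
                                        params$pause_range_s[2])
      } else {
        creaks[[length(creaks) + 1L]] <-
          c(cursor, stats::runif(1, params$creak_range_s[1],
                                 params$creak_range_s[2]))
      }
    }
  }

  st <- .add_noise(st, times, params, noise)
  for (cr in creaks) {
    sel <- which(abs(times - cr[1]) <= cr[2] / 2)
    if (length(sel) >= 2L) {
      st[sel] <- st[sel] + params$creak_depth_st *
        (-1)^(seq_along(sel)) * stats::runif(length(sel), 0.8, 1.2)
    }
  }

  if (identical(label$planted_exclusion, "no_pattern")) {
    # downward octave jump over ~100 ms, an archetypal tracking failure
    i0 <- sample(seq(ceiling(length(st) * 0.2), floor(length(st) * 0.7)), 1L)
    sel <- i0:min(length(st), i0 + round(0.1 * fs))
    st[sel] <- st[sel] - 12
  }

  .label_contour(label, times, base * 2^(st / 12))
}

.add_noise <- function(st, times, params, noise) {
  if (!noise) return(st)
  phase <- stats::runif(1, 0, 2 * pi)
  st + params$tremor_depth_st * sin(2 * pi * params$tremor_hz * times + phase) +
    stats::rnorm(length(st), 0, params$jitter_st)
}

.label_contour <- function(label, times, f0) {
  f0_contour(times = times, f0_hz = f0, voiced = rep(TRUE, length(times)),
             vocalization_id = label$vocalization_id,
             infant_id = label$infant_id, sex = label$sex,
             age_days = label$age_days, voc_type = label$voc_type,
             manual_no_pattern = FALSE)
}

#' Generate a seeded synthetic corpus with ground truth
#'
#' Builds the full corpus defined by a [corpus_composition()]: per-cell
#' (infant x month) included counts exactly as configured, ground-truth
#' categories apportioned to the mixture by the largest-remainder rule within
#' each cell (deterministic, so configured shares hold up to integer
#' rounding), vocalization types apportioned to the per-stratum ratios, and
#' excluded records (too-short and no-pattern plantings) distributed over the
#' cells proportionally to their size. Every contour is reproducible from the
#' composition seed; changing the seed changes contours but no count.
#'
#' @param comp A [corpus_composition()].
#' @param progress Print a progress line every 1000 contours.
#' @return A list of class `melody_corpus` with `contours` (list of
#'   [f0_contour()]), `labels` (ground-truth data frame) and `composition`.
#' @export
generate_corpus <- function(comp = corpus_composition(), progress = FALSE) {
  labels <- with_seed(comp$seed, .corpus_labels(comp))
  contours <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    contours[[i]] <- generate_vocalization(labels[i, ], comp$params)
    if (progress && i %% 1000L == 0L) {
      message("generated ", i, "/", nrow(labels), " contours")
    }
  }
  names(contours) <- labels$vocalization_id
  structure(list(contours = contours, labels = labels, composition = comp),
            class = "melody_corpus")
}

# ground-truth label table; all randomness is drawn under the caller's seed
.corpus_labels <- function(comp) {
  counts <- comp$counts
  infants <- rownames(counts)
  cells <- which(counts > 0, arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  cell_n <- counts[cells]
  n_inc <- sum(cell_n)
  exc_cell <- apportion_largest_remainder(comp$n_excluded, cell_n / n_inc)

  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    inf <- infants[cells[ci, 1L]]
    month <- cells[ci, 2L]
    nc <- cell_n[ci]
    ne <- exc_cell[ci]
    ratio <- if (month <= 6L) comp$type_ratio_early else comp$type_ratio_late

    cat_n <- apportion_largest_remainder(nc, comp$mixture)
    cats <- sample(rep(names(cat_n), cat_n))
    types <- sample(rep(names(ratio), apportion_largest_remainder(nc, ratio)))
    exc_n <- apportion_largest_remainder(
      ne, c(too_short = comp$too_short_frac,
            no_pattern = 1 - comp$too_short_frac))
    exc_reason <- sample(rep(names(exc_n), exc_n))
    exc_types <- sample(rep(names(ratio),
                            apportion_largest_remainder(ne, ratio)))

    n_all <- nc + ne
    day_lo <- (month - 1L) * 30L + 1L
    day_hi <- if (month == 12L) 373L else month * 30L
    df <- data.frame(
      infant_id = inf, sex = comp$sex[[inf]],
      age_days = sample(day_lo:day_hi, n_all, replace = TRUE),
      voc_type = c(types, exc_types),
      true_category = c(cats, rep(NA_character_, ne)),
      planted_exclusion = c(rep("none", nc), exc_reason)
    )
    df$true_n_arcs <- NA_integer_
    df$true_n_segmentations <- 0L
    inc_idx <- seq_len(nc)
    df$true_n_arcs[inc_idx] <- vapply(df$true_category[inc_idx], function(ct) {
      switch(ct, SA = 1L, DA = 2L, TA = 3L,
             MA = sample(4:6, 1L),
             SEG = NA_integer_)  # filled below
    }, integer(1))
    seg <- which(!is.na(df$true_category) & df$true_category == "SEG")
    for (s in seg) {
      ns <- sample(1:2, 1L)
      df$true_n_segmentations[s] <- ns
      df$true_n_arcs[s] <- min(6L, ns + 1L + sample(0:2, 1L))
    }
    df$vocalization_id <- sprintf("%s_m%02d_%04d", inf, month, seq_len(n_all))
    rows[[ci]] <- df
  }
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  labels$age_months <- age_months_from_days(labels$age_days)
  labels$seed <- as.integer((as.double(comp$seed) + 7919 *
                               seq_len(nrow(labels))) %% 2147483646 + 1)
  labels[, c("vocalization_id", "infant_id", "sex", "age_days", "age_months",
             "voc_type", "true_category", "true_n_arcs",
             "true_n_segmentations", "planted_exclusion", "seed")]
}

#' @export
print.melody_corpus <- function(x, ...) {
  lb <- x$labels
  cat(sprintf("synthetic melody corpus: %d vocalizations (%d infants), %d planted-included\n",
              nrow(lb), length(unique(lb$infant_id)),
              sum(lb$planted_exclusion == "none")))
  cat("  ground-truth mixture target:",
      paste(names(x$composition$mixture),
            sprintf("%.0f%%", 100 * x$composition$mixture), collapse = " "),
      "\n")
  invisible(x)
}

#' Write ground-truth labels as TSV
#'
#' @param corpus A `melody_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(corpus, path) {
  utils::write.table(corpus$labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate binary complexity outcomes from a mixed logistic model
#'
#' Draws per-infant random intercepts and Bernoulli outcomes from
#' `logit p = beta0 + beta_age * age + beta_type * type + b_infant`,
#' independent of the contour pipeline. Used for parameter-recovery and
#' type-I-error checks of [fit_complexity_glmm()].
#'
#' @param n_infants,n_per_infant Number of infants and observations each.
#' @param beta0,beta_age,beta_type Fixed-effect coefficients (logit scale);
#'   age is drawn uniformly from months 1--6, type is a balanced two-level
#'   factor.
#' @param re_sd Random-intercept standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A data frame with `infant_id`, `age_months`, `voc_type`,
#'   `complexity`.
#' @export
simulate_complexity_outcomes <- function(n_infants = 10, n_per_infant = 500,
                                         beta0 = 0, beta_age = 0,
                                         beta_type = 0, re_sd = 0, seed = 1) {
  stopifnot(n_infants >= 1, n_per_infant >= 1, re_sd >= 0)
  with_seed(seed, {
    b <- stats::rnorm(n_infants, 0, re_sd)
    n <- n_infants * n_per_infant
    infant <- rep(seq_len(n_infants), each = n_per_infant)
    age <- sample(1:6, n, replace = TRUE)
    type <- sample(0:1, n, replace = TRUE)
    p <- stats::plogis(beta0 + beta_age * age + beta_type * type + b[infant])
    data.frame(infant_id = sprintf("inf%02d", infant), age_months = age,
               voc_type = factor(c("t0", "t1")[type + 1L]),
               complexity = stats::rbinom(n, 1, p))
  })
}
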