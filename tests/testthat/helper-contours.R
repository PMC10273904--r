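# Builders for hand-constructed test contours. Everything is derived from
# closed-form curves so expected arc/event counts are known by construction,
# independently of the pipeline under test.

# contour from a semitone curve around a base frequency
st_contour <- function(times, st, base_hz = 440, voiced = rep(TRUE, length(times)),
                       id = "test", voc_type = "C", age_days = 40, ...) {
  f0_contour(times = times, f0_hz = base_hz * 2^(st / 12), voiced = voiced,
             vocalization_id = id, voc_type = voc_type, age_days = age_days, ...)
}

# unit raised-cosine bump with peak at fraction q of [0, 1]
rc_bump <- function(x, q = 0.5) {
  ifelse(x <= q,
         0.5 * (1 - cos(pi * x / q)),
         0.5 * (1 + cos(pi * (x - q) / (1 - q))))
}

# concatenate arcs (fm in st, duration in s) into one voiced stretch;
# optional complete pauses (unvoiced time gaps) after given arc indices
multi_arc_st <- function(fms, durs, qs = rep(0.5, length(fms)), fs = 200,
                         pause_after = integer(0), pause_s = 0.1) {
  times <- numeric(0); st <- numeric(0); cursor <- 0
  for (k in seq_along(fms)) {
    n_k <- round(durs[k] * fs) + 1L
    tt <- cursor + (seq_len(n_k) - 1L) / fs
    ss <- fms[k] * rc_bump(seq(0, 1, length.out = n_k), qs[k])
    if (k > 1L && !((k - 1L) %in% pause_after)) { tt <- tt[-1L]; ss <- ss[-1L] }
    times <- c(times, tt); st <- c(st, ss)
    cursor <- tt[length(tt)]
    if (k %in% pause_after) cursor <- cursor + pause_s
  }
  list(times = times, st = st)
}

# a ground-truth label row for the generator
make_label <- function(id = "v1", voc_type = "C", category = "SA", n_arcs = 1L,
                       n_seg = 0L, excl = "none", seed = 1L, age_days = 40L) {
  if (voc_type %in% c("BM", "BC") && age_days < 181L) age_days <- 250L
  list(vocalization_id = id, infant_id = "infA", sex = "female",
       age_days = age_days, voc_type = voc_type, true_category = category,
       true_n_arcs = n_arcs, true_n_segmentations = n_seg,
       planted_exclusion = excl, seed = seed)
}

# small corpus composition for fast end-to-end tests
small_composition <- function(seed = 11L, scale = 10L, n_excluded = 170L) {
  cnt <- melodyarc:::.default_counts()
  cnt[] <- pmax(0L, cnt %/% scale)
  corpus_composition(seed = seed, counts = cnt, n_excluded = n_excluded)
}
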