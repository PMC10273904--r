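test_that("inclusion filter applies the inclusive 300 ms bound on voiced duration", {
  cfg <- melody_config()
  # exactly 0.300 s of voiced material: excluded (bound is 'at most 300 ms')
  tt <- (0:60) / 200
  ct <- st_contour(tt, 5 * rc_bump(tt / 0.3))
  expect_identical(apply_inclusion_filter(ct, cfg),
                   list(included = FALSE, reason = "too_short"))
  # just above the bound: included
  tt2 <- (0:61) / 200
  ct2 <- st_contour(tt2, 5 * rc_bump(tt2 / 0.305))
  expect_true(apply_inclusion_filter(ct2, cfg)$included)
  # voiced duration is what counts, not total span: a long contour whose
  # voiced samples cover <= 300 ms is still too short
  tt3 <- (0:200) / 200
  ct3 <- st_contour(tt3, 5 * rc_bump(tt3), voiced = tt3 <= 0.3)
  expect_identical(apply_inclusion_filter(ct3, cfg)$reason, "too_short")
})

test_that("no-pattern exclusion fires on manual flag and sudden f0 shifts", {
  cfg <- melody_config()
  tt <- (0:200) / 200
  st <- 5 * rc_bump(tt)
  expect_identical(apply_inclusion_filter(st_contour(tt, st), cfg)$reason,
                   "none")
  ct_flag <- st_contour(tt, st, manual_no_pattern = TRUE)
  expect_identical(apply_inclusion_filter(ct_flag, cfg)$reason, "no_pattern")
  # planted 8-semitone instantaneous jump
  st_jump <- st
  st_jump[100:120] <- st_jump[100:120] - 8
  expect_identical(apply_inclusion_filter(st_contour(tt, st_jump), cfg)$reason,
                   "no_pattern")
  # a step across an unvoiced gap carries no continuity expectation
  keep <- !(tt > 0.4 & tt < 0.5)
  st_gap <- st[keep] + ifelse(tt[keep] >= 0.5, -8, 0)
  expect_identical(apply_inclusion_filter(st_contour(tt[keep], st_gap),
                                          cfg)$reason, "none")
})

test_that("extrema alternate, anchor at run boundaries and count 2K+1 on K arcs", {
  cfg <- melody_config()
  # monotone rising run: boundary min and max only
  tt <- (0:100) / 200
  tr <- preprocess_contour(st_contour(tt, 4 * tt / max(tt)), cfg)
  ex <- find_extrema(tr, cfg)
  expect_identical(ex$type, c("min", "max"))
  expect_identical(ex$idx, c(1L, length(tr$times)))

  # single symmetric arc: min, max, min
  m1 <- multi_arc_st(5, 0.8)
  ex1 <- find_extrema(preprocess_contour(st_contour(m1$times, m1$st), cfg), cfg)
  expect_identical(ex1$type, c("min", "max", "min"))

  # K noise-free arcs give exactly 2K+1 alternating extrema
  for (K in 2:5) {
    mk <- multi_arc_st(fms = seq(3, 5, length.out = K), durs = rep(0.6, K))
    exk <- find_extrema(preprocess_contour(st_contour(mk$times, mk$st), cfg),
                        cfg)
    expect_identical(nrow(exk), 2L * K + 1L)
    expect_true(all(exk$type == rep(c("min", "max"), length.out = 2 * K + 1)))
  }
})

test_that("arc extraction enforces the type-specific FM criteria", {
  cfg <- melody_config()
  # single 0.8 s, 5 st rise-fall for cry: one symmetric arc
  m <- multi_arc_st(5, 0.8)
  tr <- preprocess_contour(st_contour(m$times, m$st), cfg)
  arcs <- extract_arcs(tr, "C", cfg)
  expect_identical(nrow(arcs), 1L)
  expect_identical(arcs$shape, "symmetric")
  expect_equal(arcs$duration, 0.8, tolerance = 0.02)
  expect_equal(arcs$fm_st, 5, tolerance = 0.05)

  # second arc at 1.9 st: below the 2 st cry criterion (merged to one arc),
  # at or above the 1 st babbling criterion (two arcs)
  m2 <- multi_arc_st(c(5, 1.9), c(0.8, 0.7))
  ct2 <- st_contour(m2$times, m2$st)
  tr2 <- preprocess_contour(ct2, cfg)
  expect_identical(nrow(extract_arcs(tr2, "C", cfg)), 1L)
  expect_identical(nrow(extract_arcs(tr2, "BM", cfg)), 2L)
  expect_identical(nrow(extract_arcs(tr2, "NC", cfg)), 2L)  # 1.9 >= 1.5

  # FM exactly at the criterion passes (the bound is a minimum); measured on
  # the unsmoothed track, where the constructed amplitude is exact
  m3 <- multi_arc_st(c(5, 2), c(0.8, 0.7))
  tr3 <- resample_uniform(st_contour(m3$times, m3$st), cfg)
  expect_identical(nrow(extract_arcs(tr3, "C", cfg)), 2L)
})

test_that("arc duration criterion is strict: exactly 300 ms is not an arc", {
  cfg <- melody_config()
  # exact boundary on the unsmoothed grid, where junctions sit on samples
  m <- multi_arc_st(c(5, 5), c(0.8, 0.3))
  tr <- resample_uniform(st_contour(m$times, m$st), cfg)
  expect_identical(nrow(extract_arcs(tr, "C", cfg)), 1L)
  # comfortably above the bound, through the full pipeline
  m2 <- multi_arc_st(c(5, 5), c(0.8, 0.35))
  tr2 <- preprocess_contour(st_contour(m2$times, m2$st), cfg)
  expect_identical(nrow(extract_arcs(tr2, "C", cfg)), 2L)
})

test_that("shape prototypes follow the relative peak position", {
  cfg <- melody_config()
  for (spec in list(list(q = 0.25, shape = "left_accentuated"),
                    list(q = 0.5, shape = "symmetric"),
                    list(q = 0.75, shape = "right_accentuated"))) {
    m <- multi_arc_st(5, 0.8, qs = spec$q)
    arcs <- extract_arcs(preprocess_contour(st_contour(m$times, m$st), cfg),
                         "C", cfg)
    expect_identical(arcs$shape, spec$shape)
  }
  expect_identical(classify_arc_shape(0, 0.5, 1), "symmetric")
  expect_identical(classify_arc_shape(0, 0.2, 1), "left_accentuated")
  expect_identical(classify_arc_shape(0, 0.8, 1), "right_accentuated")
})

test_that("a flat run longer than 300 ms yields a plateau arc", {
  cfg <- melody_config()
  tt <- (0:160) / 200
  ct <- st_contour(tt, 0.4 * tt / max(tt))  # 0.4 st drift, below any criterion
  arcs <- extract_arcs(preprocess_contour(ct, cfg), "BM", cfg)
  expect_identical(nrow(arcs), 1L)
  expect_identical(arcs$shape, "plateau")
  cls <- classify_melody(arcs, NULL)
  expect_identical(cls$category, "SA")
  expect_identical(cls$complexity, 0L)
})

test_that("segmentation events: internal pauses and planted creak", {
  cfg <- melody_config()
  # one 120 ms internal gap -> one complete event
  m <- multi_arc_st(c(5, 4), c(0.6, 0.6), pause_after = 1, pause_s = 0.12)
  ct <- st_contour(m$times, m$st)
  tr <- preprocess_contour(ct, cfg)
  ev <- detect_segmentation_events(tr, ct, cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "complete")
  expect_equal(ev$gap_duration_s, 0.12, tolerance = 0.02)

  # planted 80 ms alternating +-1.5 st creak -> one incomplete event
  m2 <- multi_arc_st(c(5, 4), c(0.6, 0.6))
  st2 <- m2$st
  creak <- abs(m2$times - 0.6) <= 0.04
  st2[creak] <- st2[creak] + 1.5 * (-1)^(seq_len(sum(creak)))
  ct2 <- st_contour(m2$times, st2)
  ev2 <- detect_segmentation_events(preprocess_contour(ct2, cfg), ct2, cfg)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$kind, "incomplete")
  expect_equal(ev2$t, 0.6, tolerance = 0.05)

  # clean contour: no events
  ev3 <- detect_segmentation_events(preprocess_contour(ct2, cfg),
                                    st_contour(m2$times, m2$st), cfg)
  expect_identical(nrow(ev3), 0L)

  # an over-long internal silence is flagged for review, not counted
  m4 <- multi_arc_st(c(5, 4), c(0.6, 0.6), pause_after = 1, pause_s = 0.4)
  ct4 <- st_contour(m4$times, m4$st)
  ev4 <- detect_segmentation_events(preprocess_contour(ct4, cfg), ct4, cfg)
  expect_identical(nrow(ev4), 0L)
  expect_equal(attr(ev4, "truncation_gaps"), 0.4, tolerance = 0.02)
})

test_that("category assignment partitions by arc count with SEG precedence", {
  arc_rows <- function(n) data.frame(t_start = seq_len(n), t_peak = seq_len(n) + 0.4,
                                     t_end = seq_len(n) + 0.8)
  ev_rows <- function(n) data.frame(t = seq_len(n), kind = rep("complete", n))
  expect_identical(classify_melody(arc_rows(1), NULL)$category, "SA")
  expect_identical(classify_melody(arc_rows(1), NULL)$complexity, 0L)
  expect_identical(classify_melody(arc_rows(2), NULL)$category, "DA")
  expect_identical(classify_melody(arc_rows(3), NULL)$category, "TA")
  expect_identical(classify_melody(arc_rows(4), NULL)$category, "MA")
  expect_identical(classify_melody(arc_rows(6), NULL)$category, "MA")
  # SEG is independent of arc numbers
  seg <- classify_melody(arc_rows(3), ev_rows(1))
  expect_identical(seg$category, "SEG")
  expect_identical(seg$complexity, 1L)
  expect_identical(classify_melody(arc_rows(1), ev_rows(2))$category, "SEG")
  excl <- classify_melody(NULL, NULL, included = FALSE, reason = "too_short")
  expect_identical(excl$category, "excluded")
  expect_true(is.na(excl$complexity))
})

test_that("a segmented cry fixture classifies SEG with all structure recovered", {
  # arc - pause - arc - creak - double arc: 4 arcs, 2 segmentation events
  cfg <- melody_config()
  m <- multi_arc_st(fms = c(5, 4, 4.5, 3.5), durs = c(0.6, 0.6, 0.55, 0.55),
                    qs = c(0.5, 0.75, 0.75, 0.5),
                    pause_after = 1, pause_s = 0.12)
  st <- m$st
  # incomplete constriction at the junction between arc 2 and the double arc
  # (arc1 0.6 s + 0.12 s pause + arc2 0.6 s)
  j <- 0.6 + 0.12 + 0.6
  creak <- abs(m$times - j) <= 0.04
  st[creak] <- st[creak] + 1.5 * (-1)^(seq_len(sum(creak)))
  ct <- st_contour(m$times, st)
  res <- classify_vocalization(ct, cfg)
  expect_identical(res$category, "SEG")
  expect_identical(res$n_arcs, 4L)
  expect_identical(res$n_segmentations, 2L)
  expect_identical(res$complexity, 1L)
})

test_that("lowering the FM criterion never decreases the arc count", {
  cfg <- melody_config()
  set.seed(31)
  for (rep in 1:12) {
    K <- sample(1:4, 1)
    m <- multi_arc_st(fms = runif(K, 0.8, 4), durs = runif(K, 0.4, 0.9),
                      qs = sample(c(0.25, 0.5, 0.75), K, replace = TRUE))
    st <- m$st + rnorm(length(m$st), 0, 0.08)
    tr <- preprocess_contour(st_contour(m$times, st), cfg)
    counts <- vapply(c("C", "NC", "BM"), function(vt) {
      nrow(extract_arcs(tr, vt, cfg))
    }, integer(1))
    # thresholds C 2.0 > NC 1.5 > BM 1.0
    expect_true(counts[["NC"]] >= counts[["C"]])
    expect_true(counts[["BM"]] >= counts[["NC"]])
  }
})
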