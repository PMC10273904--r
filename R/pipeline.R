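#' Classify one vocalization end to end
#'
#' Runs the full per-vocalization pipeline: inclusion filter, semitone
#' resampling, Gaussian smoothing, arc decomposition, segmentation-event
#' detection and category assignment.
#'
#' @param contour An [f0_contour()].
#' @param config A [melody_config()].
#' @return A one-row data frame with the vocalization's metadata and its
#'   `included`, `exclusion_reason`, `n_arcs`, `n_segmentations`, `category`
#'   and `complexity` fields.
#' @export
classify_vocalization <- function(contour, config = melody_config()) {
  incl <- apply_inclusion_filter(contour, config)
  if (!incl$included) {
    cls <- classify_melody(NULL, NULL, FALSE, incl$reason)
  } else {
    track <- preprocess_contour(contour, config)
    arcs <- extract_arcs(track, contour$voc_type, config)
    events <- detect_segmentation_events(track, contour, config)
    cls <- classify_melody(arcs, events, TRUE, "none")
  }
  data.frame(vocalization_id = contour$vocalization_id,
             infant_id = contour$infant_id, sex = contour$sex,
             age_days = contour$age_days, age_months = contour$age_months,
             voc_type = contour$voc_type, included = cls$included,
             exclusion_reason = cls$exclusion_reason, n_arcs = cls$n_arcs,
             n_segmentations = cls$n_segmentations, category = cls$category,
             complexity = cls$complexity)
}

#' Classify every vocalization of a corpus
#'
#' @param corpus A `melody_corpus` (see [generate_corpus()]) or a plain list
#'   of [f0_contour()] objects.
#' @param config A [melody_config()].
#' @param progress Print a progress line every 1000 vocalizations.
#' @return A data frame with one row per vocalization, in input order, of
#'   class `melody_classifications`.
#' @export
classify_corpus <- function(corpus, config = melody_config(),
                            progress = FALSE) {
  contours <- if (inherits(corpus, "melody_corpus")) corpus$contours else corpus
  n <- length(contours)
  if (n == 0L) stop("empty corpus", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- classify_vocalization(contours[[i]], config)
    if (progress && i %% 1000L == 0L) {
      message("classified ", i, "/", n, " vocalizations")
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("melody_classifications", "data.frame")
  res
}

#' @export
print.melody_classifications <- function(x, ...) {
  n <- nrow(x)
  inc <- sum(x$included)
  cat(sprintf("melody classifications: %d vocalizations, %d included (%.1f%%)\n",
              n, inc, 100 * inc / n))
  if (inc > 0L) {
    shares <- 100 * table(factor(x$category[x$included],
                                 levels = c("SA", "DA", "TA", "MA", "SEG"))) / inc
    cat("  category shares (% of included):\n")
    print(round(shares, 1))
  }
  invisible(x)
}
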