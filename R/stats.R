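#' Developmental profiles of melody structure
#'
#' Aggregates classified vocalizations into per-(month x type) shares of the
#' five melody categories among included vocalizations, the way developmental
#' diagrams display them, plus an overall row.
#'
#' @param classifications A data frame from [classify_corpus()] (or
#'   [read_classification_table()]).
#' @param stratum `"all"`, `"early"` (months 1--6, C/NC) or `"late"` (months
#'   7--12, BM/BC).
#' @return A data frame with columns `age_months`, `voc_type`, `n`, category
#'   shares `SA`..`SEG` in percent and `complex` (= 100 - SA share). The
#'   overall row has `age_months = NA`, `voc_type = "all"`.
#' @export
build_profiles <- function(classifications, stratum = c("all", "early", "late")) {
  stratum <- match.arg(stratum)
  cls <- as.data.frame(classifications)
  cls <- cls[cls$included, , drop = FALSE]
  cls <- switch(stratum,
                all = cls,
                early = cls[cls$age_months <= 6 & cls$voc_type %in% c("C", "NC"), ],
                late = cls[cls$age_months >= 7 & cls$voc_type %in% c("BM", "BC"), ])
  cats <- c("SA", "DA", "TA", "MA", "SEG")
  if (nrow(cls) == 0L) {
    warning("no included vocalizations in stratum '", stratum, "'")
    return(data.frame(age_months = integer(0), voc_type = character(0),
                      n = integer(0), SA = numeric(0), DA = numeric(0),
                      TA = numeric(0), MA = numeric(0), SEG = numeric(0),
                      complex = numeric(0)))
  }
  share_row <- function(d) {
    tab <- table(factor(d$category, levels = cats))
    sh <- 100 * as.numeric(tab) / nrow(d)
    c(list(n = nrow(d)), stats::setNames(as.list(sh), cats),
      list(complex = 100 - sh[1L]))
  }
  grp <- split(cls, list(cls$age_months, cls$voc_type), drop = TRUE)
  rows <- lapply(grp, function(d) {
    data.frame(age_months = d$age_months[1L], voc_type = d$voc_type[1L],
               share_row(d))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age_months, out$voc_type), ]
  overall <- data.frame(age_months = NA_integer_, voc_type = "all",
                        share_row(cls))
  out <- rbind(out, overall)
  rownames(out) <- NULL
  out
}

#' Overall category shares of a classified corpus
#'
#' @param classifications A data frame from [classify_corpus()].
#' @return Named numeric vector of percentages (`SA`, `DA`, `TA`, `MA`,
#'   `SEG`, `complex`) among included vocalizations.
#' @export
category_shares <- function(classifications) {
  pr <- build_profiles(classifications, "all")
  ov <- pr[nrow(pr), ]
  stats::setNames(as.numeric(ov[c("SA", "DA", "TA", "MA", "SEG", "complex")]),
                  c("SA", "DA", "TA", "MA", "SEG", "complex"))
}

#' Mixed-effects logistic model of melody complexity
#'
#' Fits a generalized linear mixed model for the dichotomous melody-complexity
#' outcome (0 = single-arc, 1 = complex) with age in months as a metric fixed
#' effect, vocalization type as a categorical fixed effect (reference-cell
#' coding; first level is the reference) and a per-infant random intercept,
#' on a logit link via [lme4::glmer()] (Laplace approximation).
#'
#' @param data A data frame with columns `complexity` (0/1), `age_months`,
#'   `voc_type` and `infant_id`; rows with `included == FALSE` (if present)
#'   are dropped. At least two infants are required, otherwise the random
#'   intercept is unidentifiable.
#' @param stratum Optional label stored with the result (e.g.
#'   `"months 1-6 C/NC"`).
#' @return An object of class `complexity_glmm` with components
#'   `coefficients` (estimate/SE/z/p matrix), `re_var` and `re_sd` (random
#'   intercept variance and s.d.), `aic`, `n_obs`, `n_infants`, `converged`
#'   and the underlying `model`.
#' @export
#' @examples
#' sim <- simulate_complexity_outcomes(6, 80, beta_age = 0.4, re_sd = 0.3,
#'                                     seed = 42)
#' fit <- fit_complexity_glmm(sim)
#' coef(fit)["age_months"]
fit_complexity_glmm <- function(data, stratum = NULL) {
  df <- as.data.frame(data)
  if (!is.null(df$included)) df <- df[df$included, , drop = FALSE]
  need <- c("complexity", "age_months", "voc_type", "infant_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[!is.na(df$complexity), , drop = FALSE]
  if (length(unique(df$infant_id)) < 2L) {
    stop("at least two infants are required: the per-infant random ",
         "intercept is unidentifiable from a single infant", call. = FALSE)
  }
  df$voc_type <- droplevels(factor(df$voc_type))
  form <- if (nlevels(df$voc_type) >= 2L) {
    complexity ~ age_months + voc_type + (1 | infant_id)
  } else {
    complexity ~ age_months + (1 | infant_id)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = df, family = stats::binomial())
  ))
  # a boundary (singular) fit is a converged answer with zero variance;
  # only optimiser failures count as non-convergence
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- isTRUE(fit@optinfo$conv$opt == 0) &&
    !any(grepl("failed to converge|unable to evaluate|degenerate",
               msgs, ignore.case = TRUE))
  sm <- summary(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = sm$coefficients,
                 re_var = vc$vcov[1L], re_sd = vc$sdcor[1L],
                 aic = stats::AIC(fit), n_obs = nrow(df),
                 n_infants = length(unique(df$infant_id)),
                 converged = converged, stratum = stratum, model = fit),
            class = "complexity_glmm")
}

#' Fit the two age-stratum complexity models of a classified corpus
#'
#' Months 1--6 (cry vs early non-cry) and months 7--12 (marginal vs canonical
#' babbling) are modelled separately; each stratum keeps only its own
#' vocalization types.
#'
#' @param classifications A data frame from [classify_corpus()].
#' @return A named list with elements `early` and `late`, each a
#'   `complexity_glmm` (or `NULL` with a warning if a stratum is too small to
#'   fit).
#' @export
fit_complexity_models <- function(classifications) {
  cls <- as.data.frame(classifications)
  cls <- cls[cls$included, , drop = FALSE]
  strata <- list(
    early = cls[cls$age_months <= 6 & cls$voc_type %in% c("C", "NC"), ],
    late = cls[cls$age_months >= 7 & cls$voc_type %in% c("BM", "BC"), ]
  )
  labels <- c(early = "months 1-6 C/NC", late = "months 7-12 BM/BC")
  out <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 10L || length(unique(d$infant_id)) < 2L) {
      warning("stratum '", labels[[nm]], "' too small to fit (",
              nrow(d), " rows); skipped")
      return(NULL)
    }
    d$voc_type <- factor(d$voc_type,
                         levels = if (nm == "early") c("C", "NC")
                                  else c("BM", "BC"))
    fit_complexity_glmm(d, stratum = labels[[nm]])
  })
  stats::setNames(out, names(strata))
}

#' @export
print.complexity_glmm <- function(x, ...) {
  cat("Mixed-effects logistic model of melody complexity")
  if (!is.null(x$stratum)) cat(" (", x$stratum, ")", sep = "")
  cat("\n")
  cat(sprintf("  n = %d vocalizations, %d infants; AIC = %.3f%s\n",
              x$n_obs, x$n_infants, x$aic,
              if (!x$converged) " [did not converge]" else ""))
  cat(sprintf("  random intercept (infant): variance %.4f (sd %.4f)\n",
              x$re_var, x$re_sd))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.complexity_glmm <- function(object, ...) object

#' @export
coef.complexity_glmm <- function(object, ...) {
  stats::setNames(object$coefficients[, "Estimate"],
                  rownames(object$coefficients))
}

#' @export
vcov.complexity_glmm <- function(object, ...) as.matrix(stats::vcov(object$model))

#' Write a plain-text model report
#'
#' @param models A list from [fit_complexity_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(models, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  sink(con)
  on.exit(sink(), add = TRUE, after = FALSE)
  cat("Melody complexity models\n========================\n\n")
  for (nm in names(models)) {
    if (is.null(models[[nm]])) {
      cat("stratum", nm, ": skipped (insufficient data)\n\n")
    } else {
      print(models[[nm]])
      cat("\n")
    }
  }
  invisible(path)
}
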