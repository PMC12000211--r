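#' Empirical response-time quantiles
#'
#' Quantiles by linear interpolation of order statistics
#' (\code{stats::quantile} type 7), the convention used for every
#' quantile slot in the summary layouts. Stated explicitly because
#' quantile conventions differ across ecosystems.
#'
#' @param rts Non-empty numeric vector of response times (seconds).
#' @param probs Probabilities in (0, 1), sorted; defaults to the five
#'   summary quantiles .1, .3, .5, .7, .9.
#' @return Numeric vector of quantiles, non-decreasing.
#' @export
rt_quantiles <- function(rts, probs = c(.1, .3, .5, .7, .9)) {
  if (length(rts) == 0) stop("empty response-time vector")
  stopifnot(all(probs > 0), all(probs < 1), !is.unsorted(probs))
  unname(quantile(rts, probs = probs, type = 7, names = FALSE))
}

summary_probs <- c(.1, .3, .5, .7, .9)

# Fast 15-slot summary from raw vectors. Censored trials must already be
# excluded. Returns the vector plus an imputation flag.
summary15 <- function(rt, correct) {
  rc <- rt[correct]
  re <- rt[!correct]
  imputed <- length(rc) == 0L || length(re) == 0L
  if (length(rc) == 0L) rc <- re  # all-error table: copy across
  if (length(re) == 0L) re <- rc  # all-correct table: copy across
  v <- c(mean(correct),
         min(rc), min(re),
         mean(rc), mean(re),
         rt_quantiles(rc), rt_quantiles(re))
  list(values = v, imputed = imputed)
}

summary15_names <- function() {
  c("acc", "rt_min_correct", "rt_min_error", "rt_mean_correct",
    "rt_mean_error",
    paste0("q", summary_probs * 100, "_correct"),
    paste0("q", summary_probs * 100, "_error"))
}

#' Single-condition 15-slot summary vector
#'
#' Summarizes one simulated (or observed) participant's trials in a fixed
#' 15-slot layout: mean accuracy; minimum response time for correct and
#' error responses (the minimum helps identify non-decision time); mean
#' response time for correct and error responses; and the five response
#' time quantiles (.1, .3, .5, .7, .9) for correct and error responses.
#' Censored trials are excluded. When a response type is empty (e.g. an
#' all-correct table), its RT slots are copied from the other response
#' type and the vector is flagged via the \code{"imputed"} attribute;
#' copying keeps the inputs finite without inventing a sentinel scale.
#'
#' @param trials A trial table with columns \code{rt}, \code{correct} and
#'   optionally \code{censored}.
#' @return Named numeric vector of length 15 with attributes
#'   \code{"imputed"} (logical) and \code{"layout"} (\code{"single15"}).
#' @export
summarize_single_condition <- function(trials) {
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  if (nrow(trials) == 0L) stop("no uncensored trials to summarize")
  s <- summary15(trials$rt, trials$correct)
  structure(stats::setNames(s$values, summary15_names()),
            imputed = s$imputed, layout = "single15")
}

# Fast 8-slot per-condition block: mean accuracy, mean RT correct, mean RT
# error, five quantiles of the pooled (correct + error) RT distribution.
summary8 <- function(rt, correct) {
  rc <- rt[correct]
  re <- rt[!correct]
  imputed <- length(rc) == 0L || length(re) == 0L
  if (length(rc) == 0L) rc <- re
  if (length(re) == 0L) re <- rc
  list(values = c(mean(correct), mean(rc), mean(re), rt_quantiles(rt)),
       imputed = imputed)
}

#' Design-wide summary vector (8 slots per condition)
#'
#' Concatenates, for every condition of the design in canonical order
#' (lexicographic by coherence, match, discriminability), an 8-slot block:
#' mean accuracy, mean RT for corrects and for incorrects, and the five
#' response time quantiles (.1, .3, .5, .7, .9) of the condition's pooled
#' RT distribution. The 12-condition application design therefore yields a
#' 96-input vector. Minimum RT is part of the single-condition layout
#' only. The quantiles are computed on the pooled correct-plus-error
#' distribution: that is the only reading under which 8 slots x 12
#' conditions matches the 96-input layout.
#'
#' @param trials A trial table with columns \code{condition}, \code{rt},
#'   \code{correct} (and optionally \code{censored}).
#' @param design A [design_spec()]; every design condition must be present
#'   in \code{trials}.
#' @return Named numeric vector of length \code{8 * nrow(design)} with
#'   attributes \code{"imputed"} and \code{"layout"} (\code{"design"}).
#' @export
summarize_design <- function(trials, design) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  missing <- setdiff(design$condition, unique(trials$condition))
  if (length(missing)) {
    stop("conditions absent from trials: ", paste(missing, collapse = ", "))
  }
  blocks <- lapply(design$condition, function(cnd) {
    idx <- trials$condition == cnd
    summary8(trials$rt[idx], trials$correct[idx])
  })
  nms <- as.vector(vapply(design$condition, function(cnd) {
    paste0(cnd, "_", c("acc", "rt_mean_correct", "rt_mean_error",
                       paste0("q", summary_probs * 100)))
  }, character(8)))
  structure(stats::setNames(unlist(lapply(blocks, `[[`, "values")), nms),
            imputed = any(vapply(blocks, `[[`, logical(1), "imputed")),
            layout = "design")
}
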