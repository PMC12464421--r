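#' Reverse-exclusion screening statistics
#'
#' In the reverse-exclusion workflow the detector only knows the benign class
#' ("melanocytic nevus"). An image in which a nevus is confidently detected is
#' labelled low-risk; an image with no confident detection is labelled
#' high-risk (non-nevus, refer for biopsy). On a melanoma-only test cohort the
#' safety-critical error is the false negative: a melanoma called a nevus.
#' The false-negative rate is `FNR = FN / (TP + FN)`, where TP counts
#' melanomas correctly flagged as non-nevus. (Clinical summaries sometimes
#' label those correctly excluded cases "TN"; both labels are printed in the
#' summary.) The clinical safety ceiling used throughout is `FNR <= 0.5%`.
#'
#' @name screening
NULL

#' Screening decision for one image
#'
#' @param dets Detector output for one image: a data frame with a `score`
#'   column (possibly zero rows), as returned by [detector_infer()].
#' @param conf_thresh Confidence threshold; the comparison is inclusive
#'   (`>=`), so a detection at exactly 0.5 counts as a nevus call.
#' @param image_id Optional identifier carried into the result.
#' @return A one-row data frame with columns `image_id`, `label`
#'   (`"low_risk"` or `"high_risk"`) and `top_confidence` (`NA` if no
#'   detections).
#' @export
reverse_exclude <- function(dets, conf_thresh = 0.5, image_id = NA_character_) {
  scores <- if (NROW(dets) > 0) dets$score else numeric(0)
  top <- if (length(scores)) max(scores) else NA_real_
  low <- length(scores) > 0 && any(scores >= conf_thresh)
  data.frame(image_id = image_id,
             label = if (low) "low_risk" else "high_risk",
             top_confidence = top)
}

#' Reverse-exclusion confusion counts
#'
#' @param n_melanoma Total melanomas in the cohort.
#' @param fn Melanomas misclassified as nevus (false negatives).
#' @param tp Melanomas correctly flagged non-nevus; defaults to
#'   `n_melanoma - fn`.
#' @return A list with class `screening_counts`.
#' @export
screening_counts <- function(n_melanoma, fn, tp = n_melanoma - fn) {
  stopifnot(fn >= 0, tp >= 0)
  if (fn + tp != n_melanoma) stop("counts must satisfy fn + tp == n_melanoma")
  structure(list(n_melanoma = n_melanoma, fn = fn, tp = tp),
            class = "screening_counts")
}

#' False-negative rate
#'
#' @param counts A [screening_counts()] object, or a list with `fn` and `tp`.
#' @return FNR as a fraction in `[0, 1]` (`FN / (TP + FN)`).
#' @examples
#' fnr(screening_counts(365, fn = 1)) # 0.0027...
#' @export
fnr <- function(counts) {
  n <- counts$fn + counts$tp
  if (n <= 0) stop("FNR undefined for an empty cohort")
  counts$fn / n
}

#' FNR as a percentage rounded to two decimals
#'
#' @inheritParams fnr
#' @return A number like `0.27` (percent).
#' @export
fnr_percent <- function(counts) round(100 * fnr(counts), 2)

#' Clinical safety check on the FNR
#'
#' @param fnr_value FNR as a fraction.
#' @param ceiling Safety ceiling (default 0.005, i.e. 0.5%); the comparison is
#'   inclusive.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
safety_check <- function(fnr_value, ceiling = 0.005) {
  stopifnot(fnr_value >= 0, fnr_value <= 1)
  fnr_value <= ceiling
}

#' Exact McNemar test on paired miss flags
#'
#' Compares the model against a reader over the same cases using the exact
#' binomial test on discordant pairs: `b` cases the model got right but the
#' reader missed, `c` cases the model missed but the reader got right.
#'
#' @param model_miss,reader_miss Equal-length logical vectors; `TRUE` marks a
#'   missed melanoma.
#' @return Two-sided exact p-value; `1` when there are no discordant pairs.
#' @export
mcnemar_exact <- function(model_miss, reader_miss) {
  stopifnot(length(model_miss) == length(reader_miss))
  b <- sum(!model_miss & reader_miss)
  cc <- sum(model_miss & !reader_miss)
  if (b + cc == 0) return(1)
  stats::binom.test(b, b + cc, p = 0.5)$p.value
}

#' Screen a cohort of detector outputs
#'
#' Applies [reverse_exclude()] per image and, when the cohort is known to be
#' melanoma-only, tallies the reverse-exclusion confusion counts.
#'
#' @param det_list Named list of per-image detector outputs (data frames with
#'   a `score` column).
#' @param conf_thresh Confidence threshold (inclusive).
#' @param melanoma_cohort If `TRUE`, every image is a biopsy-confirmed
#'   melanoma and counts/FNR are computed.
#' @return A list with `decisions` (data frame), and when `melanoma_cohort`,
#'   `counts`, `fnr`, `fnr_percent`, `safety_pass`.
#' @export
screen_cohort <- function(det_list, conf_thresh = 0.5, melanoma_cohort = TRUE) {
  ids <- names(det_list)
  if (is.null(ids)) ids <- as.character(seq_along(det_list))
  decisions <- do.call(rbind, Map(function(d, id) {
    reverse_exclude(d, conf_thresh, image_id = id)
  }, det_list, ids))
  out <- list(decisions = decisions)
  if (melanoma_cohort && nrow(decisions) > 0) {
    fn <- sum(decisions$label == "low_risk")
    cnt <- screening_counts(nrow(decisions), fn = fn)
    out$counts <- cnt
    out$fnr <- fnr(cnt)
    out$fnr_percent <- fnr_percent(cnt)
    out$safety_pass <- safety_check(out$fnr)
  }
  out
}

#' @export
print.screening_counts <- function(x, ...) {
  cat("Reverse-exclusion screening counts\n")
  cat(sprintf("  melanomas:               %d\n", x$n_melanoma))
  cat(sprintf("  excluded (TP, aka 'TN'): %d\n", x$tp))
  cat(sprintf("  missed as nevus (FN):    %d\n", x$fn))
  cat(sprintf("  FNR: %.2f%% (ceiling 0.50%%: %s)\n", 100 * fnr(x),
              if (safety_check(fnr(x))) "pass" else "FAIL"))
  invisible(x)
}
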