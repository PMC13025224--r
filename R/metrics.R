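# Confusion-derived metrics, subject-level majority voting, confidence
# intervals and per-channel accuracy analysis. Responder (R) is the positive
# class throughout: TP = responder image predicted responder.

#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative counts; responder is the positive class.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers",
                                             call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Tabulate confusion counts from labels
#'
#' @param truth,prediction Vectors of `"R"`/`"NR"` labels.
#' @return A [confusion_counts()].
#' @export
confusion_from_labels <- function(truth, prediction) {
  truth <- as.character(truth); prediction <- as.character(prediction)
  confusion_counts(TP = sum(truth == "R" & prediction == "R"),
                   TN = sum(truth == "NR" & prediction == "NR"),
                   FP = sum(truth == "NR" & prediction == "R"),
                   FN = sum(truth == "R" & prediction == "NR"))
}

#' Performance metrics from a confusion table
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1, all as
#' percentages. A metric whose denominator is zero is reported as 0 and
#' flagged in the `undefined` attribute with a warning.
#'
#' @param cm A [confusion_counts()].
#' @return Named numeric vector of class `metric_set` (values in `[0, 100]`)
#'   with attribute `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  undefined <- character()
  safe <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(0) }
    100 * num / den
  }
  acc <- safe(tp + tn, total, "accuracy")
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  spec <- safe(tn, tn + fp, "specificity")
  f1 <- if (prec + rec == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * prec * rec / (prec + rec)
  if (length(undefined))
    warning(sprintf("undefined metric(s) reported as 0: %s",
                    paste(undefined, collapse = ", ")))
  structure(c(accuracy = acc, precision = prec, recall = rec,
              specificity = spec, f1 = f1),
            undefined = undefined, class = "metric_set")
}

#' Subject-level majority voting over image predictions
#'
#' Each subject's label is the modal predicted class over that subject's
#' images. Exact ties break to `"NR"` (the conservative, clinically cautious
#' call) and are counted in the `n_ties` attribute.
#'
#' @param subject_ids Subject id per image.
#' @param predictions Predicted `"R"`/`"NR"` label per image.
#' @return Named character vector of per-subject labels with attribute
#'   `n_ties`.
#' @export
majority_vote <- function(subject_ids, predictions) {
  subject_ids <- as.character(subject_ids)
  predictions <- as.character(predictions)
  if (length(subject_ids) != length(predictions) || length(subject_ids) == 0L)
    stop("need one prediction per image for at least one image", call. = FALSE)
  ties <- 0L
  out <- vapply(split(predictions, subject_ids), function(p) {
    nr <- sum(p == "R")
    nn <- sum(p == "NR")
    if (nr == nn) { ties <<- ties + 1L; "NR" }
    else if (nr > nn) "R" else "NR"
  }, character(1L))
  attr(out, "n_ties") <- ties
  out
}

#' Mean, SD and t-based 95% confidence interval of fold accuracies
#'
#' @param fold_accuracies Per-fold subject-level accuracies (percent),
#'   at least two folds for a CI.
#' @param conf Confidence level (default 0.95).
#' @return List with `mean`, `sd`, `ci_low`, `ci_high` (the latter `NA` for a
#'   single fold).
#' @export
subject_accuracy_ci <- function(fold_accuracies, conf = 0.95) {
  n <- length(fold_accuracies)
  if (n < 1L) stop("need at least one fold accuracy", call. = FALSE)
  m <- mean(fold_accuracies)
  if (n < 2L)
    return(list(mean = m, sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  s <- stats::sd(fold_accuracies)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) * s / sqrt(n)
  list(mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Per-channel subject-level accuracy
#'
#' Restricts the image predictions to each channel in turn, majority-votes
#' per subject within that channel, and scores the votes against the subject
#' truth; channels with no images get `NA`.
#'
#' @param meta Data frame with one row per image: columns `subject_id`,
#'   `channel` and `truth` (subject class label).
#' @param predictions Predicted label per image.
#' @param channels Channels to report (default: all present).
#' @return Named numeric vector of per-channel subject accuracies in percent.
#' @export
per_channel_accuracy <- function(meta, predictions, channels = NULL) {
  stopifnot(all(c("subject_id", "channel", "truth") %in% names(meta)))
  if (nrow(meta) != length(predictions))
    stop("need one prediction per image", call. = FALSE)
  if (is.null(channels)) channels <- unique(meta$channel)
  truth_by_subject <- tapply(as.character(meta$truth), meta$subject_id,
                             function(x) x[1L])
  out <- stats::setNames(rep(NA_real_, length(channels)), channels)
  for (ch in channels) {
    sel <- meta$channel == ch
    if (!any(sel)) next
    votes <- majority_vote(meta$subject_id[sel], predictions[sel])
    out[ch] <- 100 * mean(votes == truth_by_subject[names(votes)])
  }
  out
}
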