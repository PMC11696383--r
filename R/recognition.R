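#' Threshold classifier over a profile table
#'
#' Each character is assigned to its own class when its mean amplitude
#' strictly exceeds `A_th` (mV) and its mean period strictly exceeds `P_th`
#' (s); otherwise it is rejected.  The thresholds are deliberate inputs with
#' no defaults — the published analysis defines the rule but not the values.
#'
#' @param profiles A `profile_table`.
#' @param A_th Amplitude threshold, mV, `>= 0`.
#' @param P_th Period threshold, s, `>= 0`.
#' @return Character vector over the 26 letters (named by letter): the
#'   predicted label, or `"REJECT"`.
#' @export
threshold_classify <- function(profiles, A_th, P_th) {
  stopifnot(inherits(profiles, "profile_table"))
  if (A_th < 0 || P_th < 0) stop("thresholds must be >= 0")
  pred <- ifelse(profiles$amp_mean > A_th & profiles$per_mean > P_th,
                 profiles$label, "REJECT")
  stats::setNames(pred, profiles$label)
}

#' Build a confusion matrix with a reject tally
#'
#' Counts (true, predicted) label pairs into a 26 x 26 matrix; rejected
#' instances are tallied per true class in a separate vector so the matrix
#' keeps its square shape.
#'
#' @param true_labels Character vector of true labels, `A`-`Z`.
#' @param predicted_labels Same-length character vector of predicted labels
#'   (`A`-`Z`) or `"REJECT"`.
#' @return A `confusion_matrix`: list with `counts` (26 x 26 integer matrix,
#'   rows = true, columns = predicted) and `rejected` (length-26 integer
#'   vector by true class).
#' @export
build_confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  bad <- setdiff(unique(true_labels), LETTERS)
  if (length(bad) > 0L) {
    stop("true label outside A-Z: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(predicted_labels), c(LETTERS, "REJECT"))
  if (length(bad) > 0L) {
    stop("predicted label outside A-Z/REJECT: ", paste(bad, collapse = ", "))
  }
  counts <- matrix(0L, 26L, 26L, dimnames = list(true = LETTERS,
                                                 predicted = LETTERS))
  rejected <- stats::setNames(integer(26L), LETTERS)
  keep <- predicted_labels != "REJECT"
  if (any(keep)) {
    tab <- table(factor(true_labels[keep], levels = LETTERS),
                 factor(predicted_labels[keep], levels = LETTERS))
    counts[] <- as.integer(tab)
  }
  if (any(!keep)) {
    rej <- table(factor(true_labels[!keep], levels = LETTERS))
    rejected[] <- as.integer(rej)
  }
  structure(list(counts = counts, rejected = rejected),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  total <- sum(x$counts) + sum(x$rejected)
  cat(sprintf("<confusion_matrix> %d instance(s): %d classified (%d correct), %d rejected\n",
              total, sum(x$counts), sum(diag(x$counts)), sum(x$rejected)))
  invisible(x)
}

cm_total <- function(cm) sum(cm$counts) + sum(cm$rejected)

#' Classification accuracy
#'
#' Diagonal mass over all instances, rejected ones included in the
#' denominator (a reject is never a correct classification).
#'
#' @param cm A [build_confusion_matrix()] result.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm_total(cm)
  if (total == 0L) stop("confusion matrix holds no instances")
  sum(diag(cm$counts)) / total
}

#' Per-class precision and recall
#'
#' Precision is the correct fraction of predictions of the class (column
#' sum); recall the correct fraction of true instances of the class, with
#' rejected instances of that class counted in the denominator.  When a
#' denominator is zero the metric is undefined and reported as `NA`, never
#' silently as 0.
#'
#' @param cm A [build_confusion_matrix()] result.
#' @param class Letter(s) to evaluate; default all 26.
#' @return Data frame with columns `class`, `precision`, `recall`.
#' @export
precision_recall <- function(cm, class = LETTERS) {
  stopifnot(inherits(cm, "confusion_matrix"))
  class <- match.arg(class, LETTERS, several.ok = TRUE)
  res <- lapply(class, function(cl) {
    tp <- cm$counts[cl, cl]
    pred_total <- sum(cm$counts[, cl])
    true_total <- sum(cm$counts[cl, ]) + cm$rejected[[cl]]
    data.frame(class = cl,
               precision = if (pred_total > 0) tp / pred_total else NA_real_,
               recall = if (true_total > 0) tp / true_total else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Nearest-profile classifier
#'
#' Assigns an observed character profile to the reference row minimizing
#' Euclidean distance in the (mean amplitude, mean period) plane after
#' per-feature z-scoring across the 26 references.  A feature that is
#' constant across the references carries no information and is dropped;
#' distance ties resolve to the alphabetically first label.
#'
#' @param observed A [character_profile()].
#' @param references A `profile_table`.
#' @param scaling `"zscore"` (default) or `"none"`.
#' @return The winning reference label (single character).
#' @export
nearest_profile_classify <- function(observed, references,
                                     scaling = c("zscore", "none")) {
  stopifnot(inherits(observed, "character_profile"),
            inherits(references, "profile_table"))
  scaling <- match.arg(scaling)
  feats <- cbind(amp = references$amp_mean, per = references$per_mean)
  obs <- c(amp = observed$amplitude$mean, per = observed$period$mean)
  if (scaling == "zscore") {
    centre <- colMeans(feats)
    scale <- apply(feats, 2L, stats::sd)
    keep <- scale > 0
    feats <- sweep(sweep(feats[, keep, drop = FALSE], 2L, centre[keep]),
                   2L, scale[keep], "/")
    obs <- (obs[keep] - centre[keep]) / scale[keep]
  }
  d2 <- if (ncol(feats) == 0L) rep(0, nrow(references)) else
    colSums((t(feats) - obs)^2)
  references$label[which.min(d2)]  # which.min takes the first (alphabetical) tie
}
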