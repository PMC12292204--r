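#' Area under the ROC curve
#'
#' Rank-based implementation equal to the probability that a randomly
#' chosen positive trial receives a higher score than a randomly chosen
#' negative one, with ties counted one half (the Mann-Whitney statistic).
#'
#' @param scores numeric risk-class scores, higher = more positive.
#' @param labels binary labels: logical, 0/1 numeric, or a two-level
#'   factor (second level = positive class).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes must be present to compute ROC AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_e` comes
#' from the product of the marginal distributions.  If both marginals are
#' degenerate (`p_e = 1`) the statistic is undefined and returned as 0
#' with a warning.
#'
#' @param predictions,labels equal-length vectors of class assignments.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(rep(c(1, 0), c(50, 50)), rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))
#' @export
cohen_kappa <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), length(labels) > 0)
  lev <- sort(unique(c(as.character(predictions), as.character(labels))))
  p <- factor(as.character(predictions), levels = lev)
  l <- factor(as.character(labels), levels = lev)
  tab <- table(p, l)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Sensitivity (true-positive rate)
#'
#' @param predictions,labels class assignments.
#' @param positive the positive (risk) class label.
#' @return `tp / (tp + fn)`.
#' @export
sensitivity <- function(predictions, labels, positive) {
  stopifnot(length(predictions) == length(labels))
  pos <- labels == positive
  if (!any(pos)) stop("no positive labels present", call. = FALSE)
  sum(predictions[pos] == positive) / sum(pos)
}

#' Confusion counts for a binary problem
#'
#' @inheritParams sensitivity
#' @return Named vector `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predictions, labels, positive) {
  stopifnot(length(predictions) == length(labels))
  pp <- predictions == positive
  lp <- labels == positive
  c(tp = sum(pp & lp), fp = sum(pp & !lp),
    fn = sum(!pp & lp), tn = sum(!pp & !lp))
}

#' Landis-Koch agreement band for a kappa value
#'
#' The kappa value is rounded half-up to two decimals, then banded with
#' left-closed intervals: below 0 `"poor"`, 0.00--0.20 `"slight"`,
#' 0.21--0.40 `"fair"`, 0.41--0.60 `"moderate"`, 0.61--0.80
#' `"substantial"`, 0.81--1.00 `"almost perfect"`.
#'
#' @param kappa value in \[-1, 1\].
#' @return Character band label.
#' @examples
#' agreement_band(0.22)  # "fair"
#' @export
agreement_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1 - 1e-9, kappa <= 1 + 1e-9)
  k <- floor(kappa * 100 + 0.5) / 100      # round half up at 2 decimals
  if (k < 0) "poor"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

# Coerce labels to integer 0/1 with 1 = positive class.
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have two levels", call. = FALSE)
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (all(u %in% c(0, 1))) return(as.integer(labels))
  if (length(u) == 2L) return(as.integer(labels == u[2]))
  stop("cannot interpret labels as binary", call. = FALSE)
}
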