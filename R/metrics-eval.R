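# Binary prediction evaluation: AUC, confusion matrix / MCC, Brier score,
# and the predicted-vs-observed significance test.

.check_eval <- function(p, o) {
  if (length(p) != length(o)) stop("predictions and outcomes differ in length")
  if (length(p) < 1) stop("empty evaluation set")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("prediction probabilities must lie in [0, 1]")
  }
  if (!all(o %in% c(0, 1))) stop("outcomes must be binary 0/1")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' presence receives a higher score than a randomly chosen absence, ties
#' counted one half.
#'
#' @param p Prediction scores/probabilities.
#' @param o Binary outcomes (0/1); both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(p, o) {
  .check_eval(p, o)
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single outcome class")
  r <- rank(p, ties.method = "average")
  (sum(r[o == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix at a probability threshold
#'
#' A station is predicted present iff its probability strictly exceeds the
#' threshold.
#'
#' @param p Prediction probabilities.
#' @param o Binary outcomes.
#' @param threshold Classification threshold in (0, 1); default 0.5.
#' @return List with integer `TP`, `TN`, `FP`, `FN` (class
#'   `confusion_matrix`).
#' @export
confusion <- function(p, o, threshold = 0.5) {
  .check_eval(p, o)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pred <- p > threshold
  structure(
    list(
      TP = sum(pred & o == 1), TN = sum(!pred & o == 0),
      FP = sum(pred & o == 0), FN = sum(!pred & o == 1)
    ),
    class = "confusion_matrix"
  )
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor of
#' the denominator is zero the coefficient is defined as 0 and flagged via
#' the `"degenerate"` attribute.
#'
#' @param cm A [confusion()] matrix (or list with TP/TN/FP/FN).
#' @return MCC in [-1, 1].
#' @export
mcc <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be nonnegative")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  # double precision: counts are small integers, products stay exact
  (tp * tn - fp * fn) / sqrt(den)
}

#' Brier score
#'
#' Mean squared difference between forecast probability and outcome:
#' `(1/N) sum (p_i - o_i)^2`. Lower is better; 0 is a perfect forecast.
#'
#' @param p Prediction probabilities.
#' @param o Binary outcomes.
#' @return Brier score in [0, 1].
#' @export
brier <- function(p, o) {
  .check_eval(p, o)
  mean((p - o)^2)
}

#' Summary evaluation report
#'
#' @param p Prediction probabilities.
#' @param o Binary outcomes.
#' @param threshold Threshold for the MCC confusion matrix.
#' @return data.frame with `auc`, `brier`, `mcc`, `threshold`, `n`.
#' @export
metrics_report <- function(p, o, threshold = 0.5) {
  data.frame(
    auc = auc(p, o), brier = brier(p, o),
    mcc = as.numeric(mcc(confusion(p, o, threshold))),
    threshold = threshold, n = length(p)
  )
}

#' Predicted-versus-observed significance test
#'
#' Two-sided paired t test of predicted station values against observed
#' values; a nonsignificant result indicates no systematic disagreement.
#' For the two-group comparison the one-way ANOVA F statistic equals the
#' square of the unpaired t statistic; this identity is computed alongside
#' and verified internally.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3).
#' @return List with `t` (paired t), `p_value`, `df`, and the unpaired
#'   `f_anova`/`t_unpaired` pair.
#' @export
pred_obs_test <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  d <- predicted - observed
  if (all(d == 0)) {
    # identical vectors: no disagreement at all
    return(list(t = 0, p_value = 1, df = length(d) - 1,
                t_unpaired = 0, f_anova = 0))
  }
  if (stats::sd(d) == 0) {
    stop("zero variance of differences; test degenerate")
  }
  tt <- stats::t.test(predicted, observed, paired = TRUE)
  ut <- stats::t.test(predicted, observed, var.equal = TRUE)
  grp <- factor(rep(c("pred", "obs"), c(length(predicted), length(observed))))
  fv <- summary(stats::aov(c(predicted, observed) ~ grp))[[1]]$`F value`[1]
  if (abs(fv - ut$statistic^2) > 1e-8 * max(1, fv)) {
    warning("ANOVA F != t^2; numerical inconsistency")
  }
  list(
    t = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter),
    t_unpaired = unname(ut$statistic), f_anova = fv
  )
}
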