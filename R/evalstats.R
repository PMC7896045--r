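## ROC/AUC evaluation: Mann-Whitney AUC, DeLong confidence intervals and
## paired two-sided tests, bootstrap AUC distributions with box-whisker
## summaries, and one-vs-rest scoring of ternary outputs.

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation; tied scores count one half.
#'
#' @param labels binary 0/1 vector (1 = positive); both classes must occur.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10[i] = mean_j psi(x_i, y_j) over negatives,
# V01[j] = mean_i psi(x_i, y_j) over positives, psi = 1 / 0.5 / 0 for
# x > y / x == y / x < y.
delong_components <- function(labels, scores) {
  x <- scores[labels == 1]
  y <- scores[labels != 1]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi),
       auc = mean(psi), m = length(x), n = length(y))
}

#' DeLong confidence interval for an AUC
#'
#' Variance from the structural components, normal-approximation interval
#' clipped to [0, 1]. Perfect separation has zero component variance and
#' degenerates to a zero-width interval, with a warning.
#'
#' @param labels,scores as in [auc()].
#' @param level confidence level.
#' @return list with `auc`, `ci_low`, `ci_high`, `var`, `level`.
#' @export
delong_ci <- function(labels, scores, level = 0.95) {
  dc <- delong_components(labels, scores)
  # a single positive (or negative) contributes no estimable component
  # variance; its term is 0
  v10 <- if (dc$m > 1) var(dc$v10) else 0
  v01 <- if (dc$n > 1) var(dc$v01) else 0
  v <- v10 / dc$m + v01 / dc$n
  if (v == 0) warning("zero DeLong variance (perfect separation); degenerate CI")
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = dc$auc, ci_low = max(0, dc$auc - z * sqrt(v)),
       ci_high = min(1, dc$auc + z * sqrt(v)), var = v, level = level)
}

#' Paired two-sided DeLong test
#'
#' Compares the AUCs of two models scored on the same cases; the variance of
#' the AUC difference uses the paired covariance of the structural
#' components. Identical score vectors give p = 1.
#'
#' @param labels shared binary labels.
#' @param scores_a,scores_b paired score vectors.
#' @return list with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) ||
      length(labels) != length(scores_a))
    stop("DeLong test requires paired scores on identical cases")
  a <- delong_components(labels, scores_a)
  b <- delong_components(labels, scores_b)
  s10 <- if (a$m > 1) cov(cbind(a$v10, b$v10)) else matrix(0, 2, 2)
  s01 <- if (a$n > 1) cov(cbind(a$v01, b$v01)) else matrix(0, 2, 2)
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  d <- a$auc - b$auc
  z <- if (v > 0) d / sqrt(v) else 0
  list(p_value = if (d == 0) 1 else 2 * pnorm(-abs(z)),
       auc_a = a$auc, auc_b = b$auc, z = z)
}

#' Bootstrap AUC distribution with box-whisker summary
#'
#' Resamples cases with replacement `n_iter` times; resamples missing a class
#' are redrawn (seeded) so the iteration count stays exact. The box-whisker
#' summary takes whiskers at the most extreme observed AUCs within
#' Q2 +/- 1.5 * (Q3 - Q1).
#'
#' @param labels,scores as in [auc()].
#' @param n_iter bootstrap iterations (default 100).
#' @param seed seed.
#' @return list with `aucs`, quartiles `q1`, `q2`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n_iter`.
#' @export
bootstrap_auc <- function(labels, scores, n_iter = 100L, seed = 1L) {
  n <- length(labels)
  aucs <- with_seed(derive_seed(seed, "bootstrap-auc"), {
    vapply(seq_len(n_iter), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2)
          return(auc(labels[idx], scores[idx]))
      }
    }, numeric(1))
  })
  q <- quantile(aucs, c(0.25, 0.5, 0.75), names = FALSE)
  lo_lim <- q[2] - 1.5 * (q[3] - q[1])
  hi_lim <- q[2] + 1.5 * (q[3] - q[1])
  inside <- aucs[aucs >= lo_lim & aucs <= hi_lim]
  list(aucs = aucs, q1 = q[1], q2 = q[2], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = aucs[aucs < lo_lim | aucs > hi_lim],
       n_iter = as.integer(n_iter))
}

#' Null-reference model scores
#'
#' The uninformative reference that always returns probability 0.5; useful
#' as the null hypothesis when asking whether a model's AUC is significantly
#' above chance.
#'
#' @param n number of cases.
#' @return numeric vector of 0.5s.
#' @export
null_model_scores <- function(n) rep(0.5, n)

#' One-vs-rest scored cases from ternary outputs
#'
#' The score for a target cancer class is its softmax probability, untouched
#' (no renormalization); the binary label is 1 iff the slide label equals the
#' target.
#'
#' @param probs n x 3 matrix of class probabilities (columns NC, ADC, SqCC).
#' @param labels character slide labels.
#' @param target "ADC" or "SqCC".
#' @return data.frame with `label` (0/1) and `score`.
#' @export
one_vs_rest <- function(probs, labels, target = c("ADC", "SqCC")) {
  target <- match.arg(target)
  stopifnot(nrow(probs) == length(labels), nrow(probs) > 0)
  data.frame(label = as.integer(labels == target),
             score = probs[, match(target, CLASS_LEVELS)])
}
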