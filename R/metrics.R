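#' Pearson correlation between predicted and recorded responses
#'
#' A thin, validating wrapper: errors (rather than silently returning 0 or
#' NA) when either series is constant, since a correlation is then undefined.
#'
#' @param pred,real Equal-length numeric vectors, length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(pred, real) {
  pred <- as.numeric(pred); real <- as.numeric(real)
  if (length(pred) != length(real)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(real)))
    stop("non-finite values")
  if (sd(pred) == 0 || sd(real) == 0)
    stop("correlation undefined: zero variance in ",
         if (sd(pred) == 0) "pred" else "real")
  cor(pred, real)
}

#' Peak tuning index (PT)
#'
#' A membership metric for the top of the tuning curve: the threshold `t` is
#' the smallest of the top-`top_fraction` recorded responses, and PT is the
#' percentage of the "top predictions" whose value reaches `t`. In `"joint"`
#' mode (PTJ) the candidate set is the images with the top recorded
#' responses; in `"separate"` mode (PTS) it is the images with the top
#' predicted responses, rank ordered independently of the recordings. PTJ is
#' the stricter measure. Ties at either threshold are all included
#' (inclusive `>=`), so with heavily tied data the candidate set can exceed
#' `ceiling(top_fraction * n)`.
#'
#' @param pred,real Equal-length response vectors.
#' @param top_fraction Fraction defining the peak (default 0.01, i.e. top 1%).
#' @param mode `"joint"` or `"separate"`.
#' @param joint_rule For joint mode: `"threshold"` (count candidate images
#'   whose prediction reaches `t`; the printed-formula reading, default) or
#'   `"rank"` (count candidate images whose prediction also ranks in the top
#'   `top_fraction` of predictions).
#' @return A `sacnn_peak_tuning` list: `pt_percent`, `mode`, `top_fraction`,
#'   `threshold`, `k` (candidate-set size), `n_above`.
#' @export
peak_tuning <- function(pred, real, top_fraction = 0.01,
                        mode = c("joint", "separate"),
                        joint_rule = c("threshold", "rank")) {
  mode <- match.arg(mode)
  joint_rule <- match.arg(joint_rule)
  pred <- as.numeric(pred); real <- as.numeric(real)
  n <- length(real)
  if (n == 0 || length(pred) != n) stop("need equal-length nonempty series")
  if (!is.finite(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  k0 <- ceiling(top_fraction * n)
  t <- sort(real, decreasing = TRUE)[k0]
  members <- if (mode == "joint") which(real >= t) else {
    tp <- sort(pred, decreasing = TRUE)[k0]
    which(pred >= tp)
  }
  n_above <- if (mode == "joint" && joint_rule == "rank") {
    tp <- sort(pred, decreasing = TRUE)[k0]
    sum(pred[members] >= tp)
  } else sum(pred[members] >= t)
  structure(list(pt_percent = 100 * n_above / length(members), mode = mode,
                 top_fraction = top_fraction, threshold = t,
                 k = length(members), n_above = n_above),
            class = "sacnn_peak_tuning")
}

#' @export
print.sacnn_peak_tuning <- function(x, ...) {
  cat(sprintf("PT%s = %.1f%% (%d of %d above threshold %.4g)\n",
              if (x$mode == "joint") "J" else "S", x$pt_percent, x$n_above,
              x$k, x$threshold))
  invisible(x)
}

#' Noise-ceiling-normalized correlation (CCnorm)
#'
#' Pearson correlation between the prediction and the repeat-averaged
#' response, divided by the maximum correlation attainable given
#' trial-to-trial noise. The ceiling `CCmax = sqrt(SP / Var(ybar))` uses the
#' signal-power estimator from repeat variance,
#' `SP = (Var(rowSums(Y)) - sum(Var(Y[, r]))) / (R * (R - 1))`
#' (variances across images), which equals `Var(ybar)` when all repeats are
#' identical so that CCnorm reduces to the plain Pearson correlation.
#'
#' @param pred Predicted responses, length `n_images`.
#' @param real_repeats `n_images x n_repeats` matrix of recorded responses.
#' @return A list: `ccnorm`, `ccmax`, `cc_raw` (Pearson against the repeat
#'   mean), `signal_power`.
#' @export
normalized_correlation <- function(pred, real_repeats) {
  Y <- as.matrix(real_repeats)
  R <- ncol(Y)
  if (R < 2)
    stop("normalized correlation needs >= 2 repeats; use pearson_cor for ",
         "single-trial data")
  if (nrow(Y) != length(pred)) stop("length mismatch")
  ybar <- rowMeans(Y)
  cc <- pearson_cor(pred, ybar)
  sp <- (var(rowSums(Y)) - sum(apply(Y, 2, var))) / (R * (R - 1))
  if (sp <= 0)
    stop("signal power estimate is non-positive; repeats look like pure ",
         "noise")
  ccmax <- sqrt(sp / var(ybar))
  list(ccnorm = cc / ccmax, ccmax = ccmax, cc_raw = cc, signal_power = sp)
}

#' Rank-ordered tuning curve
#'
#' Sorts responses in descending order by the chosen key (stable; ties broken
#' by image index) for tuning-curve displays.
#'
#' @param real,pred Equal-length response vectors.
#' @param key `"real"` or `"pred"`: which series defines the rank order.
#' @return A `sacnn_tuning_curve` list: `order` (permutation of image
#'   indices), `real`, `pred` (both reordered), `key`.
#' @export
tuning_curve <- function(real, pred, key = c("real", "pred")) {
  key <- match.arg(key)
  if (length(real) != length(pred)) stop("length mismatch")
  kv <- if (key == "real") real else pred
  ord <- order(-kv, seq_along(kv))
  structure(list(order = ord, real = real[ord], pred = pred[ord], key = key),
            class = "sacnn_tuning_curve")
}
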