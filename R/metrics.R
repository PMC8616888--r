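# Uncertainty scores, directional information, coverage diagnostics, and the
# correlation metrics used by the failure-mode detection protocols.

#' Interval-width uncertainty score
#'
#' @param lo,hi Lower/upper prediction bounds (`lo <= hi` component-wise).
#' @return `hi - lo`, component-wise (nonnegative).
#' @export
uncertainty_score <- function(lo, hi) {
  check_same_shape(lo, hi, "lo", "hi")
  if (any(lo > hi)) stop_contract("`lo` must not exceed `hi`")
  hi - lo
}

#' Directionality ratio
#'
#' Per component, the ratio of the larger to the smaller part of the
#' prediction interval on either side of the prediction:
#' `DR = max(hi - pred, pred - lo) / min(hi - pred, pred - lo)`.
#' Components where the smaller part is below `tol` (prediction on an
#' interval boundary) are undefined and returned as `NA`.
#'
#' @param lo,hi Interval bounds.
#' @param pred Prediction, `lo <= pred <= hi` component-wise.
#' @param tol Degeneracy tolerance for the smaller interval part.
#' @return Array of ratios `>= 1`, `NA` where undefined.
#' @export
directionality_ratio <- function(lo, hi, pred, tol = 1e-12) {
  check_same_shape(lo, pred, "lo", "pred")
  check_same_shape(hi, pred, "hi", "pred")
  if (any(pred < lo) || any(pred > hi)) {
    stop_contract("`pred` must lie inside [lo, hi] component-wise")
  }
  upper_part <- hi - pred
  lower_part <- pred - lo
  small <- pmin(upper_part, lower_part)
  dr <- pmax(upper_part, lower_part) / small
  dr[small < tol] <- NA_real_
  dr
}

#' Directionality accuracy per directionality-ratio bin
#'
#' Bins components by their directionality ratio and reports, per bin, the
#' relative frequency of target components falling in the larger interval
#' part (targets exactly at the prediction count one half; at a symmetric
#' interval, the upper part is taken as the "larger" side). Components with
#' undefined ratio are excluded. A value of 0.5 is chance level; values above
#' mean the interval's asymmetry points toward the target.
#'
#' @param lo,hi,pred As in [directionality_ratio()].
#' @param targets Target array of the same shape.
#' @param dr_bins Either a single count of log-spaced bins over
#'   `[1, max(DR)]` or an explicit vector of increasing bin edges starting
#'   at 1.
#' @param tol Degeneracy tolerance passed to [directionality_ratio()].
#' @return Data frame with `bin_lo`, `bin_hi`, `da` (NA for empty bins),
#'   `count`, and `freq` (relative frequency of components per bin).
#' @export
directionality_accuracy <- function(lo, hi, pred, targets, dr_bins = 20,
                                    tol = 1e-12) {
  check_same_shape(pred, targets, "pred", "targets")
  dr <- directionality_ratio(lo, hi, pred, tol = tol)
  ok <- !is.na(dr)
  dr <- as.numeric(dr[ok])
  upper_larger <- (hi - pred)[ok] >= (pred - lo)[ok]
  tgt <- as.numeric(targets[ok])
  prd <- as.numeric(pred[ok])
  in_larger <- ifelse(tgt == prd, 0.5,
                      ifelse(upper_larger, tgt > prd, tgt < prd))
  if (length(dr_bins) == 1) {
    hi_edge <- max(dr, 1 + 1e-9)
    edges <- exp(seq(0, log(hi_edge), length.out = dr_bins + 1))
  } else {
    edges <- dr_bins
    if (edges[1] > 1 || is.unsorted(edges, strictly = TRUE)) {
      stop_contract("`dr_bins` edges must increase and start at 1 or below")
    }
  }
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
  bin <- findInterval(dr, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  nb <- length(edges) - 1
  count <- tabulate(bin, nbins = nb)
  da <- rep(NA_real_, nb)
  for (b in which(count > 0)) {
    da[b] <- mean(in_larger[bin == b])
  }
  data.frame(
    bin_lo = edges[seq_len(nb)],
    bin_hi = edges[-1],
    da = da,
    count = count,
    freq = count / max(sum(count), 1)
  )
}

#' Empirical coverage of (enlarged) prediction intervals
#'
#' Fraction of target components strictly inside the interval enlarged by
#' `lam * beta` on both sides: `lo - lam*beta < x < hi + lam*beta`. For a
#' well-trained interval network, a Markov-inequality argument bounds the
#' population version below by `1 - 1/lam`.
#'
#' @param lo,hi Interval bounds.
#' @param targets Targets of the same shape.
#' @param lam Positive enlargement multiplier.
#' @param beta Nonnegative tightness parameter used in training.
#' @return Fraction in `[0, 1]`.
#' @export
empirical_coverage <- function(lo, hi, targets, lam, beta) {
  check_same_shape(lo, targets, "lo", "targets")
  check_same_shape(hi, targets, "hi", "targets")
  if (lam <= 0) stop_contract("`lam` must be positive")
  if (beta < 0) stop_contract("`beta` must be nonnegative")
  mean(targets > lo - lam * beta & targets < hi + lam * beta)
}

#' Performance-weighted correlation coefficient
#'
#' Pearson correlation between the component-wise absolute prediction error
#' and the uncertainty score, normalised by the mean squared error of the
#' prediction. The normalisation discourages rewarding poor predictors that
#' are uniformly uncertain. Returns `NA` when either argument is constant
#' (undefined correlation).
#'
#' @param pred,target Prediction and target arrays.
#' @param u Nonnegative uncertainty scores, same shape.
#' @return Scalar PWCC, or `NA` if undefined.
#' @export
pwcc <- function(pred, target, u) {
  check_same_shape(pred, target, "pred", "target")
  check_same_shape(pred, u, "pred", "u")
  if (length(pred) < 2) stop_contract("PWCC needs at least 2 components")
  if (any(u < 0)) stop_contract("`u` must be nonnegative")
  err <- abs(as.numeric(pred) - as.numeric(target))
  uu <- as.numeric(u)
  if (stats::sd(err) == 0 || stats::sd(uu) == 0) return(NA_real_)
  stats::cor(err, uu) / mean(err^2)
}

#' Correlation between an uncertainty-heatmap change and a change map
#'
#' Pearson correlation between `|u_ref - u_pert|` (the component-wise change
#' in the uncertainty heatmap under a perturbed input) and a change map: the
#' reconstruction change for adversarial detection, or a binary insertion
#' mask for atypical-artifact detection. Returns `NA` when either side is
#' constant; a heatmap change that is negligible relative to the heatmap's
#' own variability (below `1e-10` of it, i.e. floating-point noise from an
#' effectively unchanged input) also counts as constant. Drivers exclude
#' such samples from averaging and log the count.
#'
#' @param u_ref,u_pert Uncertainty heatmaps for the reference and perturbed
#'   input.
#' @param change_map Change map of the same shape.
#' @return Pearson correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
heatmap_change_correlation <- function(u_ref, u_pert, change_map) {
  check_same_shape(u_ref, u_pert, "u_ref", "u_pert")
  check_same_shape(u_ref, change_map, "u_ref", "change_map")
  du <- abs(as.numeric(u_ref) - as.numeric(u_pert))
  cm <- as.numeric(change_map)
  scale_ref <- stats::sd(as.numeric(u_ref)) + stats::sd(du)
  if (stats::sd(du) <= 1e-10 * scale_ref || stats::sd(cm) == 0) {
    return(NA_real_)
  }
  stats::cor(du, cm)
}

#' Assemble a per-sample uncertainty report
#'
#' Light container collecting the per-component uncertainty heatmap and the
#' scalar diagnostics computed for one sample.
#'
#' @param uncertainty Nonnegative per-component uncertainty array.
#' @param dr Optional directionality ratios.
#' @param coverage Optional named vector of empirical coverages per lambda.
#' @param pwcc Optional PWCC value.
#' @param pearson Optional heatmap-change correlation.
#' @return An object of class `uq_report`.
#' @export
uq_report <- function(uncertainty, dr = NULL, coverage = NULL, pwcc = NULL,
                      pearson = NULL) {
  if (any(uncertainty < 0)) stop_contract("`uncertainty` must be nonnegative")
  if (!is.null(coverage) && (any(coverage < 0) || any(coverage > 1))) {
    stop_contract("`coverage` must lie in [0, 1]")
  }
  structure(
    list(uncertainty = uncertainty, dr = dr, coverage = coverage,
         pwcc = pwcc, pearson = pearson),
    class = "uq_report"
  )
}
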