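#' Logit transform with boundary clamping
#'
#' Similarities of exactly 0 or 1 have no finite logit; values are clamped
#' into [eps, 1 - eps] before ln(s / (1 - s)).  The number of clamped
#' values is attached as attribute `"n_clamped"` and propagated into decay
#' fits, so boundary handling is always visible in the output.
#'
#' @param s values in [0, 1].
#' @param eps clamping margin (default 1e-3).
#' @return logit-transformed vector with attribute `n_clamped`.
#' @export
logit <- function(s, eps = 1e-3) {
  if (any(s < -1e-9 | s > 1 + 1e-9)) stop("values outside [0, 1]")
  s <- pmin(pmax(s, 0), 1)
  clamped <- s < eps | s > 1 - eps
  s <- pmin(pmax(s, eps), 1 - eps)
  structure(log(s / (1 - s)), n_clamped = sum(clamped))
}

#' Build sample pairs of similarity and spatial/temporal distance
#'
#' Similarity is 1 - Bray-Curtis.  Spatial distances are Euclidean in
#' metres from sample coordinates; temporal distances are absolute
#' differences in days between collection dates.
#'
#' @param d `dist` or symmetric Bray-Curtis matrix with sample labels.
#' @param positions for `mode = "spatial"`: data.frame with `sample_id`,
#'   `x_m`, `y_m` (or a 2-column matrix with sample rownames); for
#'   `mode = "temporal"`: data.frame with `sample_id`, `date`, or a named
#'   Date vector.
#' @param mode `"spatial"` or `"temporal"`.
#' @return data.frame of class `amf_pairs` with columns `sample_i`,
#'   `sample_j`, `similarity`, `distance`; each unordered pair once.
#' @export
build_pairs <- function(d, positions, mode = c("spatial", "temporal")) {
  mode <- match.arg(mode)
  D <- as.matrix(d)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix has no sample labels")
  if (mode == "spatial") {
    if (is.data.frame(positions)) {
      rownames(positions) <- positions$sample_id
      coords <- as.matrix(positions[, c("x_m", "y_m")])
      rownames(coords) <- positions$sample_id
    } else coords <- as.matrix(positions)
    missing <- setdiff(labels, rownames(coords))
    if (length(missing))
      stop("samples without coordinates: ", paste(missing, collapse = ", "))
    coords <- coords[labels, , drop = FALSE]
    pd <- as.matrix(stats::dist(coords))
  } else {
    if (is.data.frame(positions)) {
      dates <- as.Date(positions$date)
      names(dates) <- positions$sample_id
    } else dates <- as.Date(positions)
    missing <- setdiff(labels, names(dates))
    if (length(missing))
      stop("samples without dates: ", paste(missing, collapse = ", "))
    dates <- dates[labels]
    pd <- abs(outer(as.numeric(dates), as.numeric(dates), "-"))
  }
  n <- length(labels)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(sample_i = labels[ij[, 1]], sample_j = labels[ij[, 2]],
                    similarity = 1 - D[ij], distance = pd[ij],
                    stringsAsFactors = FALSE)
  class(out) <- c("amf_pairs", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "labels") <- labels
  out
}

#' Fit a logit-scale distance-decay model
#'
#' Ordinary least squares of logit(similarity) on pairwise distance.  The
#' decay slope is read from the model using the untransformed distance by
#' default; for model comparison the AIC (Gaussian likelihood, constant
#' included, as computed by standard model-selection conventions) is also
#' reported for a log1p-transformed distance, which accommodates
#' zero-distance pairs (e.g. samples collected on the same day).  Because
#' pairwise observations share samples and are not independent, no
#' analytic p-value is attached to the slope; use
#' [permutation_test_slope()] or [decay_test()].
#'
#' @param pairs an [build_pairs()] pair set (or data.frame with
#'   `similarity` and `distance`).
#' @param distance_transform `"none"` (default) or `"log"` (log1p).
#' @param eps clamping margin for the logit.
#' @return object of class `amf_decay` with `slope_logit`, `intercept`,
#'   `aic_untransformed`, `aic_logdistance`, `n_pairs`, `n_clamped` and
#'   the underlying `lm` fit.
#' @export
fit_decay <- function(pairs, distance_transform = c("none", "log"),
                      eps = 1e-3) {
  distance_transform <- match.arg(distance_transform)
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (length(unique(pairs$distance)) < 2)
    stop("all distances identical; decay slope undefined")
  y <- logit(pairs$similarity, eps)
  n_clamped <- attr(y, "n_clamped")
  y <- as.numeric(y)
  fit_none <- stats::lm(y ~ distance, data = data.frame(y = y,
                                                        distance = pairs$distance))
  fit_log <- stats::lm(y ~ ld, data = data.frame(y = y,
                                                 ld = log1p(pairs$distance)))
  fit <- if (distance_transform == "none") fit_none else fit_log
  structure(list(slope_logit = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 aic_untransformed = stats::AIC(fit_none),
                 aic_logdistance = stats::AIC(fit_log),
                 distance_transform = distance_transform,
                 n_pairs = nrow(pairs), n_clamped = n_clamped,
                 mode = attr(pairs, "mode"),
                 p_perm = NA_real_, n_perm = 0L,
                 model = fit),
            class = "amf_decay")
}

#' @export
print.amf_decay <- function(x, ...) {
  cat(sprintf("Distance decay (%s, logit similarity): slope = %.5g over %d pairs\n",
              if (is.null(x$mode)) "pairs" else x$mode,
              x$slope_logit, x$n_pairs))
  cat(sprintf("  AIC untransformed = %.2f, log-distance = %.2f\n",
              x$aic_untransformed, x$aic_logdistance))
  if (x$n_clamped > 0)
    cat(sprintf("  %d similarity value(s) clamped at the logit boundary\n",
                x$n_clamped))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation P = %.4g (%d label permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

# closed-form OLS slope of y on x
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Permutation test of the decay slope
#'
#' The null distribution is generated by permuting sample labels — not the
#' pairs themselves: a permutation reassigns whole samples to positions,
#' then the n(n-1)/2 pair similarities are re-matched with the fixed pair
#' distances and the slope refitted.  This preserves the dependence
#' structure among pairwise observations.  The p-value is one-sided toward
#' decay by default: p = (1 + #{beta_perm <= beta_obs}) / (1 + n_perm).
#'
#' @param pairs an [build_pairs()] pair set (must carry its sample
#'   labels).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed.
#' @param alternative `"less"` (one-sided toward a more negative slope,
#'   default) or `"two.sided"`.
#' @param eps clamping margin for the logit.
#' @param distance_transform transform for the fitted model.
#' @return `amf_decay` object with `p_perm`, `n_perm` and the permuted
#'   slopes in `perm_slopes`.
#' @export
permutation_test_slope <- function(pairs, n_perm = 999, seed = NULL,
                                   alternative = c("less", "two.sided"),
                                   eps = 1e-3,
                                   distance_transform = c("none", "log")) {
  alternative <- match.arg(alternative)
  distance_transform <- match.arg(distance_transform)
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- attr(pairs, "labels")
  if (is.null(labels))
    labels <- sort(unique(c(pairs$sample_i, pairs$sample_j)))
  n <- length(labels)
  fit <- fit_decay(pairs, distance_transform, eps)

  # logit-similarity matrix indexed by sample
  L <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  lsim <- as.numeric(logit(pairs$similarity, eps))
  ii <- match(pairs$sample_i, labels)
  jj <- match(pairs$sample_j, labels)
  L[cbind(ii, jj)] <- lsim
  L[cbind(jj, ii)] <- lsim
  x <- if (distance_transform == "none") pairs$distance
       else log1p(pairs$distance)

  if (!is.null(seed)) set.seed(seed)
  slopes <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- L[cbind(p[ii], p[jj])]
    slopes[b] <- ols_slope(x, yp)
  }
  beta <- fit$slope_logit
  p_perm <- if (alternative == "less")
    (1 + sum(slopes <= beta)) / (1 + n_perm)
  else
    (1 + sum(abs(slopes) >= abs(beta))) / (1 + n_perm)
  fit$p_perm <- p_perm
  fit$n_perm <- n_perm
  fit$alternative <- alternative
  fit$perm_slopes <- slopes
  fit
}

#' One-call distance-decay analysis
#'
#' Convenience wrapper: builds pairs from a distance matrix and positions
#' or dates, fits the logit decay model and runs the label-permutation
#' test.
#'
#' @inheritParams build_pairs
#' @inheritParams permutation_test_slope
#' @return `amf_decay` object.
#' @export
decay_test <- function(d, positions, mode = c("spatial", "temporal"),
                       n_perm = 999, seed = NULL,
                       alternative = c("less", "two.sided"), eps = 1e-3) {
  pairs <- build_pairs(d, positions, mode)
  permutation_test_slope(pairs, n_perm = n_perm, seed = seed,
                         alternative = alternative, eps = eps)
}
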