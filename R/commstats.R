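#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC(x, y) = sum_k |x_k - y_k| / sum_k (x_k + y_k).  On proportional
#' compositions (rows summing to 1) this lies in [0, 1], with 0 for
#' identical profiles and 1 for disjoint taxon support.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(x) + sum(y)
  if (denom == 0) stop("Bray-Curtis undefined: both vectors all-zero")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Because BC(x, y) = manhattan(x, y) / (sum(x) + sum(y)), the full matrix
#' is computed from the Manhattan distances and row totals.
#'
#' @param m community_matrix (proportions for the study analyses; counts
#'   are accepted and used as-is), or a plain numeric matrix with sample
#'   rownames.
#' @return object of class `dist` with sample labels.
#' @export
distance_matrix <- function(m) {
  x <- if (inherits(m, "community_matrix")) m$values else as.matrix(m)
  if (nrow(x) < 2) stop("need at least 2 samples")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ", paste(rownames(x)[rs == 0], collapse = ", "))
  man <- stats::dist(x, method = "manhattan")
  d <- man / pair_sums(rs)
  attr(d, "method") <- "bray"
  d
}

# lower-triangle vector of rs[i] + rs[j], matching dist ordering
pair_sums <- function(rs) {
  n <- length(rs)
  out <- numeric(n * (n - 1) / 2)
  k <- 1L
  for (j in 1:(n - 1)) {
    idx <- (j + 1):n
    out[k:(k + length(idx) - 1)] <- rs[j] + rs[idx]
    k <- k + length(idx)
  }
  out
}

#' Expected richness in a random subsample (analytic rarefaction)
#'
#' E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n)) for a sample with taxon
#' counts N_i summing to N.  Binomial coefficients are evaluated on the
#' log scale (`lchoose`) for numerical stability at large N.
#'
#' @param counts integer vector of taxon counts for one sample.
#' @param n subsample size, 1 <= n <= sum(counts).
#' @return expected taxon richness (real).
#' @export
rarefied_richness <- function(counts, n) {
  if (any(counts < 0)) stop("negative counts")
  N <- sum(counts)
  if (n < 1 || n > N) stop("subsample size out of range [1, ", N, "]")
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Rarefaction curve for a group of samples
#'
#' Mean expected richness across samples at each depth.  Samples whose
#' total count falls below a depth are excluded at that depth (the number
#' contributing is reported), so each point averages only samples that can
#' support the subsample.
#'
#' @param m community_matrix in counts mode.
#' @param samples sample ids forming the group (default: all).
#' @param depths integer vector of subsample sizes.
#' @return data.frame with columns `depth`, `richness`, `n_samples`.
#' @export
rarefaction_curve <- function(m, samples = NULL, depths) {
  stopifnot(inherits(m, "community_matrix"), m$mode == "counts")
  if (is.null(samples)) samples <- rownames(m$values)
  if (!length(samples)) stop("empty sample group")
  x <- m$values[samples, , drop = FALSE]
  totals <- rowSums(x)
  res <- lapply(sort(depths), function(dep) {
    usable <- which(totals >= dep)
    if (!length(usable)) return(NULL)
    vals <- vapply(usable, function(i) rarefied_richness(x[i, ], dep),
                   numeric(1))
    data.frame(depth = dep, richness = mean(vals),
               n_samples = length(usable))
  })
  do.call(rbind, res)
}

# Gower-centred inner-product matrix from squared distances;
# trace(G) = SS_total = (1/n) * sum_{i<j} d_ij^2
gower_matrix <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm <- rowMeans(A)
  A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
}

#' Distance-based permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among factors
#' using the Gower-centred inner-product matrix G: SS of a term is
#' trace(H G) for the increment H of the sequential (Type-I) projection
#' onto the cumulative model matrix; pseudo-F of each term is
#' MS_term / MS_residual.  Significance is assessed by freely permuting
#' sample labels (rows and columns of the distance matrix) and recomputing
#' each pseudo-F; p = (1 + #{F_perm >= F_obs}) / (1 + n_perm), so p is
#' never zero.
#'
#' @param d `dist` object (or symmetric matrix) with sample labels.
#' @param factors data.frame of factors, one row per sample (matched to
#'   the labels of `d` via rownames or a `sample_id` column); term order
#'   in the model follows column order.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed for the permutations.
#' @return object of class `amf_permanova`: the ANOVA-style table plus
#'   attributes.
#' @export
permanova <- function(d, factors, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples")
  labels <- rownames(D)
  factors <- as.data.frame(factors)
  if ("sample_id" %in% names(factors)) {
    rownames(factors) <- factors$sample_id
    factors$sample_id <- NULL
  }
  if (!is.null(labels) && !is.null(rownames(factors))) {
    missing <- setdiff(labels, rownames(factors))
    if (length(missing))
      stop("samples without factor levels: ",
           paste(missing, collapse = ", "))
    factors <- factors[labels, , drop = FALSE]
  } else if (nrow(factors) != n) {
    stop("factors do not match distance matrix")
  }
  terms <- names(factors)
  for (tt in terms) {
    factors[[tt]] <- factor(factors[[tt]])
    if (nlevels(factors[[tt]]) < 2)
      stop("factor '", tt, "' has a single level")
  }

  G <- gower_matrix(D)
  ss_total <- sum(diag(G))
  if (ss_total < 1e-12) stop("degenerate distance matrix: all samples identical")

  # sequential hat-matrix increments
  hats <- list()
  X <- matrix(1, n, 1)
  H_prev <- X %*% solve(crossprod(X)) %*% t(X)
  rank_prev <- 1L
  df <- integer(0)
  for (tt in terms) {
    X <- cbind(X, stats::model.matrix(~ f - 1,
                                      data.frame(f = factors[[tt]])))
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H <- tcrossprod(Q)
    hats[[tt]] <- H - H_prev
    df <- c(df, qrX$rank - rank_prev)
    H_prev <- H
    rank_prev <- qrX$rank
  }
  df_res <- n - rank_prev
  if (df_res <= 0) stop("no residual degrees of freedom")
  R <- diag(n) - H_prev

  ss_terms <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss_res <- sum(R * G)
  ms_terms <- ss_terms / df
  ms_res <- ss_res / df_res
  f_obs <- ms_terms / ms_res

  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(terms))
  if (n_perm > 0) {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      ssp <- vapply(hats, function(H) sum(H * Gp), numeric(1))
      f_p <- (ssp / df) / ((sum(R * Gp)) / df_res)
      exceed <- exceed + (f_p >= f_obs)
    }
  }
  p_perm <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    Df = c(df, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    MS = c(ms_terms, ms_res, NA),
    pseudo_F = c(f_obs, NA, NA),
    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
    p_perm = c(p_perm, NA, NA),
    row.names = c(terms, "Residuals", "Total"))
  structure(list(table = tab, n = n, n_perm = n_perm, seed = seed),
            class = "amf_permanova")
}

#' @export
print.amf_permanova <- function(x, digits = 3, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d free label permutations)\n",
              x$n_perm))
  tab <- x$table
  tab$SS <- round(tab$SS, digits)
  tab$MS <- round(tab$MS, digits)
  tab$pseudo_F <- round(tab$pseudo_F, digits)
  tab$R2 <- round(tab$R2, digits)
  print(tab)
  invisible(x)
}

#' Principal-coordinates embedding of a distance matrix
#'
#' Eigen-decomposition of the Gower-centred matrix.  Axes with positive
#' eigenvalues carry real coordinates; axes with negative eigenvalues
#' (possible for semi-metric dissimilarities such as Bray-Curtis) are kept
#' separately and contribute negatively to squared distances, following
#' the standard correction.
#'
#' @param d `dist` or symmetric matrix.
#' @param tol eigenvalues within `tol * max(|lambda|)` of zero are dropped.
#' @return list with `pos` (n x p coordinate matrix), `neg` (n x q matrix
#'   for negative axes), `eig` (all eigenvalues).
#' @export
pcoa_embed <- function(d, tol = 1e-8) {
  D <- as.matrix(d)
  G <- gower_matrix(D)
  e <- eigen(G, symmetric = TRUE)
  thr <- tol * max(abs(e$values))
  ip <- which(e$values > thr)
  im <- which(e$values < -thr)
  pos <- e$vectors[, ip, drop = FALSE] %*%
    diag(sqrt(e$values[ip]), length(ip))
  neg <- e$vectors[, im, drop = FALSE] %*%
    diag(sqrt(-e$values[im]), length(im))
  rownames(pos) <- rownames(neg) <- rownames(D)
  list(pos = pos, neg = neg, eig = e$values)
}

weiszfeld_median <- function(X, iter = 100, tol = 1e-8) {
  m <- colMeans(X)
  for (i in seq_len(iter)) {
    w <- sqrt(rowSums(sweep(X, 2, m)^2))
    w[w < 1e-12] <- 1e-12
    m_new <- colSums(X / w) / sum(1 / w)
    if (sum(abs(m_new - m)) < tol) break
    m <- m_new
  }
  m
}

#' Homogeneity of multivariate dispersions
#'
#' Distinguishes compositional (location) effects from differences in
#' within-group spread: samples are embedded by principal coordinates,
#' each sample's distance to its own group centre is computed (squared
#' contributions from negative-eigenvalue axes are subtracted and the
#' result floored at zero), and the distances are compared between groups
#' with a one-way ANOVA F on (k - 1, n - k) degrees of freedom.
#'
#' @param d `dist` or symmetric matrix with sample labels.
#' @param groups factor of group membership (named by sample, or in the
#'   order of the labels of `d`).
#' @param centre `"centroid"` (group mean in PCoA space, default) or
#'   `"median"` (spatial median on the positive axes via Weiszfeld
#'   iteration; the centroid is used on the negative axes).
#' @return object of class `amf_dispersion` with per-sample distances,
#'   group means, F, df and p.
#' @export
dispersion_test <- function(d, groups, centre = c("centroid", "median")) {
  centre <- match.arg(centre)
  D <- as.matrix(d)
  labels <- rownames(D)
  if (!is.null(names(groups)) && !is.null(labels))
    groups <- groups[labels]
  groups <- factor(groups)
  if (length(groups) != nrow(D)) stop("groups do not match distance matrix")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  emb <- pcoa_embed(D)
  n <- nrow(D); k <- nlevels(groups)
  dist_to_centre <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cp <- if (centre == "centroid") colMeans(emb$pos[idx, , drop = FALSE])
          else weiszfeld_median(emb$pos[idx, , drop = FALSE])
    cn <- colMeans(emb$neg[idx, , drop = FALSE])
    d2 <- rowSums(sweep(emb$pos[idx, , drop = FALSE], 2, cp)^2) -
      rowSums(sweep(emb$neg[idx, , drop = FALSE], 2, cn)^2)
    dist_to_centre[idx] <- sqrt(pmax(d2, 0))
  }
  gm <- c(tapply(dist_to_centre, groups, mean))
  grand <- mean(dist_to_centre)
  ssb <- sum(tabulate(groups) * (gm - grand)^2)
  ssw <- sum((dist_to_centre - gm[groups])^2)
  df1 <- k - 1; df2 <- n - k
  F <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  structure(list(distances = stats::setNames(dist_to_centre, labels),
                 group_means = gm, F = F, df1 = df1, df2 = df2, p = p,
                 centre = centre),
            class = "amf_dispersion")
}

#' @export
print.amf_dispersion <- function(x, ...) {
  cat(sprintf(
    "Homogeneity of multivariate dispersions (%s): F_%d,%d = %.3f, P = %.3g\n",
    x$centre, x$df1, x$df2, x$F, x$p))
  cat("  mean distance to group centre:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' Poisson-GLM comparison of taxon richness between groups
#'
#' Fits a log-link Poisson GLM of per-sample VT richness on the grouping
#' factor and tests it against the intercept-only model by the deviance
#' difference (likelihood-ratio chi-square on k - 1 df).
#'
#' @param richness integer vector of per-sample taxon richness.
#' @param group factor of group membership.
#' @return object of class `amf_richness` with group means (and standard
#'   errors of the mean), chi2, df and p.
#' @export
poisson_richness_test <- function(richness, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(richness < 0)) stop("negative richness")
  fit <- stats::glm(richness ~ group, family = stats::poisson())
  if (!fit$converged) stop("Poisson GLM did not converge")
  chi2 <- fit$null.deviance - fit$deviance
  df <- nlevels(group) - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  means <- c(tapply(richness, group, mean))
  ses <- c(tapply(richness, group,
                  function(v) stats::sd(v) / sqrt(length(v))))
  structure(list(group_means = means, group_se = ses,
                 chi2 = chi2, df = df, p = p),
            class = "amf_richness")
}

#' @export
print.amf_richness <- function(x, ...) {
  cat(sprintf("Poisson GLM on richness: chi2 = %.3f (df %d), P = %.3g\n",
              x$chi2, x$df, x$p))
  for (g in names(x$group_means))
    cat(sprintf("  %s: mean = %.2f, s.e. = %.2f\n",
                g, x$group_means[g], x$group_se[g]))
  invisible(x)
}

#' Observed per-sample taxon richness
#'
#' @param m community_matrix.
#' @return named integer vector, number of VT with non-zero abundance per
#'   sample.
#' @export
sample_richness <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  rowSums(m$values > 0)
}
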