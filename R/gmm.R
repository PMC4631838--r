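#' Gaussian mixture model in three dimensions
#'
#' A weighted sum of 3-D Gaussian components used both to approximate
#' electron density maps and to represent the mass distribution of model
#' components. Mixing weights are normalized to sum to 1 on construction
#' unless `normalize = FALSE` (weights are later rescaled to component
#' masses when a mixture serves as a per-module density restraint).
#'
#' @param weights numeric vector of non-negative component weights.
#' @param means n x 3 matrix of component means (Angstrom).
#' @param covs n x 3 x 3 array of symmetric positive-definite covariances.
#' @param normalize normalize weights to sum to 1 (default TRUE).
#' @return object of class `gmm`.
#' @export
gmm <- function(weights, means, covs, normalize = TRUE) {
  means <- matrix(as.numeric(means), ncol = 3)
  n <- nrow(means)
  if (length(weights) != n) stop("weights/means length mismatch")
  if (any(weights < 0)) stop("negative mixture weight")
  if (is.matrix(covs) && n == 1L) covs <- array(covs, dim = c(1, 3, 3))
  if (!all(dim(covs) == c(n, 3, 3))) stop("covs must be n x 3 x 3")
  for (i in seq_len(n)) {
    S <- covs[i, , ]
    if (max(abs(S - t(S))) > 1e-8) stop("covariance ", i, " not symmetric")
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("covariance ", i, " not positive-definite")
  }
  if (normalize) {
    s <- sum(weights)
    if (s <= 0) stop("total weight must be positive")
    weights <- weights / s
  }
  structure(list(weights = as.numeric(weights), means = means, covs = covs),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("gmm: %d component(s), total weight %.4g\n",
              length(x$weights), sum(x$weights)))
  invisible(x)
}

#' Number of Gaussian components for a structured region
#'
#' One component per 50 residues (floor division), with a minimum of one
#' component for regions shorter than 50 residues.
#'
#' @param n_residues number of residues in the component.
#' @return integer component count.
#' @export
n_gaussians_for <- function(n_residues) {
  stopifnot(n_residues >= 1)
  pmax(1L, n_residues %/% 50L)
}

#' Evaluate a GMM density at points
#' @param gmm a [gmm()].
#' @param points m x 3 matrix.
#' @return numeric vector of densities.
#' @export
gmm_density <- function(gmm, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  out <- numeric(nrow(points))
  for (i in seq_along(gmm$weights)) {
    S <- gmm$covs[i, , ]
    Sinv <- solve(S)
    dt <- det(S)
    dif <- sweep(points, 2, gmm$means[i, ], `-`)
    q <- rowSums((dif %*% Sinv) * dif)
    out <- out + gmm$weights[i] * exp(-0.5 * q) / ((2 * pi)^1.5 * sqrt(dt))
  }
  out
}

#' Fit a Gaussian mixture to weighted points by expectation-maximization
#'
#' Weighted-data EM with k-means initialization. The log-likelihood
#' (weighted by the point weights) is non-decreasing over iterations;
#' the trace is returned as attribute `loglik`. Deterministic given the
#' RNG state (set a seed before calling).
#'
#' @param points m x 3 matrix of sample positions.
#' @param weights per-point non-negative weights (default uniform).
#' @param n_components number of components (>= 1).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param reg variance floor added to covariance diagonals (A^2), guards
#'   degenerate point clouds.
#' @return a [gmm()] with attribute `loglik` (per-iteration trace).
#' @export
fit_gmm <- function(points, weights = NULL, n_components = 1,
                    max_iter = 200, tol = 1e-8, reg = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3)
  m <- nrow(points)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weights/points length mismatch")
  if (any(weights < 0)) stop("negative point weight")
  k <- as.integer(n_components)
  if (k < 1L) stop("n_components must be >= 1")
  if (m < k) stop("need at least as many points as components")
  w <- weights / sum(weights)

  spread <- if (m < 2L) 0 else
    max(stats::dist(points[seq_len(min(m, 200L)), , drop = FALSE]))
  if (spread < 1e-12 || k == 1L) {
    init_assign <- rep(1L, m)
    if (k > 1L) stop("degenerate point cloud: all points identical")
  } else {
    km <- suppressWarnings(stats::kmeans(points, centers = k, nstart = 5,
                                         iter.max = 50))
    init_assign <- km$cluster
  }
  pi_k <- vapply(seq_len(k), function(j) sum(w[init_assign == j]), numeric(1))
  pi_k <- pmax(pi_k, 1e-12); pi_k <- pi_k / sum(pi_k)
  mu <- matrix(0, k, 3)
  Sig <- array(0, dim = c(k, 3, 3))
  for (j in seq_len(k)) {
    sel <- init_assign == j
    ws <- w[sel] / sum(w[sel])
    mu[j, ] <- colSums(points[sel, , drop = FALSE] * ws)
    d <- sweep(points[sel, , drop = FALSE], 2, mu[j, ], `-`)
    Sig[j, , ] <- crossprod(d * sqrt(ws), d * sqrt(ws)) + reg * diag(3)
  }

  loglik <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E step: responsibilities (log-space for stability)
    logp <- matrix(0, m, k)
    for (j in seq_len(k)) {
      S <- Sig[j, , ]
      Sinv <- solve(S)
      dif <- sweep(points, 2, mu[j, ], `-`)
      q <- rowSums((dif %*% Sinv) * dif)
      logp[, j] <- log(pi_k[j]) - 0.5 * q - 1.5 * log(2 * pi) -
        0.5 * log(det(S))
    }
    mx <- apply(logp, 1, max)
    pse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(w * pse)
    loglik <- c(loglik, ll)
    resp <- exp(logp - pse)
    # M step (weighted)
    for (j in seq_len(k)) {
      rw <- resp[, j] * w
      nk <- sum(rw)
      if (nk < 1e-12) nk <- 1e-12
      pi_k[j] <- nk
      mu[j, ] <- colSums(points * rw) / nk
      d <- sweep(points, 2, mu[j, ], `-`)
      Sig[j, , ] <- crossprod(d * sqrt(rw / nk), d * sqrt(rw / nk)) +
        reg * diag(3)
    }
    pi_k <- pi_k / sum(pi_k)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12))
      break
    ll_old <- ll
  }
  out <- gmm(pi_k, mu, Sig)
  attr(out, "loglik") <- loglik
  out
}

#' Fit a GMM to a voxel density map
#'
#' Voxel centers with density above `threshold` are used as EM sample
#' points, weighted by their density. Fitted mixing weights sum to 1; when
#' the mixture is used as a per-module density restraint, rescale the
#' weights to the module mass with [scale_gmm_mass()].
#'
#' @param map a [voxel_map()].
#' @param n_components component count.
#' @param threshold density cutoff (default 0: all positive voxels).
#' @return a [gmm()].
#' @export
gmm_from_voxels <- function(map, n_components, threshold = 0) {
  ctr <- voxel_centers(map)
  dens <- as.numeric(map$data)
  keep <- dens > threshold
  if (!any(keep)) stop("no voxels above threshold")
  fit_gmm(ctr[keep, , drop = FALSE], dens[keep], n_components)
}

#' Rescale GMM weights to a total mass
#' @param gmm a [gmm()].
#' @param mass total mass (e.g. Da) the weights should sum to.
#' @return a [gmm()] with unnormalized weights summing to `mass`.
#' @export
scale_gmm_mass <- function(gmm, mass) {
  gmm$weights <- gmm$weights / sum(gmm$weights) * mass
  gmm
}

#' Rasterize a GMM onto a voxel grid
#'
#' @param gmm a [gmm()].
#' @param origin,spacing,dims grid specification; defaults enclose the
#'   mixture means with `pad` Angstrom of padding.
#' @param pad padding used when deriving the default grid.
#' @return a [voxel_map()] holding the mixture density at voxel centers.
#' @export
rasterize_gmm <- function(gmm, origin = NULL, spacing = 4, dims = NULL,
                          pad = 15) {
  if (is.null(origin) || is.null(dims)) {
    sd_max <- sqrt(max(apply(gmm$covs, 1, function(S) max(diag(matrix(S, 3, 3))))))
    lo <- apply(gmm$means, 2, min) - pad - 2 * sd_max
    hi <- apply(gmm$means, 2, max) + pad + 2 * sd_max
    origin <- lo
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  map <- voxel_map(array(0, dim = dims), origin = origin, spacing = spacing)
  map$data <- array(gmm_density(gmm, voxel_centers(map)), dim = dims)
  map
}

#' Apply a rigid transform to a GMM
#' @param gmm a [gmm()].
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation.
#' @param center rotation center (default origin).
#' @return transformed [gmm()].
#' @export
transform_gmm <- function(gmm, R = diag(3), t = c(0, 0, 0),
                          center = c(0, 0, 0)) {
  gmm$means <- t(R %*% (t(gmm$means) - center) + center + t)
  for (i in seq_along(gmm$weights))
    gmm$covs[i, , ] <- R %*% gmm$covs[i, , ] %*% t(R)
  gmm
}
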