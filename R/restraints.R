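#' Restraint parameters
#'
#' All scoring constants in one place. `l_xl` is the maximum Calpha-Calpha
#' reach of the cross-linker (21 A for BS3); `slope` the weak linear
#' distance prior (1/A); `em_scale` the multiplier on the negative log
#' cross-correlation; `connectivity_factor` the upper-bound multiple of the
#' summed radii for sequence-consecutive beads; `redundancy_cap` the cap on
#' the spectral-redundancy weight; `sigma_min`/`sigma_max` the support of
#' the uniform prior on the positional uncertainty radius.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
restraint_params <- function(...) {
  p <- list(l_xl = 21, slope = 0.01, em_scale = 100,
            connectivity_factor = 4, redundancy_cap = 4,
            sigma_min = 0, sigma_max = 100,
            k_excluded = 1, k_connect = 1)
  utils::modifyList(p, list(...))
}

# 16-point Gauss-Legendre nodes/weights on [0,1], computed once
# (Golub-Welsch). The forward-model integrand is piecewise polynomial of
# low degree, so this rule is exact on each piece.
.gl16 <- local({
  n <- 16
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (x + 1) / 2, w = w / 2)
})

# volume of the intersection of spheres with radii R and r, centers rho apart
.lens_volume <- function(R, r, rho) {
  if (rho >= R + r) return(0)
  if (rho <= abs(R - r)) return(4 / 3 * pi * min(R, r)^3)
  pi * (R + r - rho)^2 *
    (rho^2 + 2 * rho * r - 3 * r^2 + 2 * rho * R + 6 * r * R - 3 * R^2) /
    (12 * rho)
}

#' Cross-link forward model
#'
#' Probability that two points drawn uniformly from spheres of radii
#' `sigma_i` and `sigma_j`, centered on the two cross-linked residues a
#' distance `d` apart, lie within the maximum linker length `l_xl` of each
#' other. Evaluated from the exact distribution of the point-to-center
#' distance combined with sphere-sphere lens volumes; the integrand is
#' piecewise polynomial and integrated exactly by Gauss-Legendre quadrature
#' on the analytic breakpoints. Continuous, non-increasing in `d`,
#' non-decreasing in `l_xl`; returns exactly 0 when `d - sigma_i - sigma_j
#' > l_xl` and exactly 1 when `d + sigma_i + sigma_j <= l_xl`.
#'
#' @param d center-center distance (A), vectorized.
#' @param sigma_i,sigma_j sphere radii (A, > 0).
#' @param l_xl maximum linker length (A).
#' @return probability in \[0, 1\].
#' @export
forward_model <- function(d, sigma_i, sigma_j, l_xl = 21) {
  if (sigma_i <= 0 || sigma_j <= 0) stop("sphere radii must be > 0")
  vapply(d, .forward_model_1, numeric(1),
         a = sigma_i, b = sigma_j, L = l_xl)
}

.forward_model_1 <- function(d, a, b, L) {
  if (d < 0) stop("d must be >= 0")
  if (d - a - b > L) return(0)
  if (d + a + b <= L) return(1)
  # density of t = |X - P|, X uniform in ball(O, a), |OP| = d
  eps <- 1e-9
  if (d < eps) {
    p_t <- function(t) 3 * t^2 / a^3
    t_lo <- 0; t_hi <- a; inner_bp <- numeric(0)
  } else {
    p_t <- function(t) ifelse(t < a - d,
                              3 * t^2 / a^3,
                              3 * t * (a^2 - (d - t)^2) / (4 * a^3 * d))
    t_lo <- max(0, d - a); t_hi <- d + a
    inner_bp <- if (a > d) a - d else numeric(0)
  }
  g_t <- function(t) vapply(t, function(tt) .lens_volume(b, L, tt),
                            numeric(1)) / (4 / 3 * pi * b^3)
  bp <- sort(unique(pmin(pmax(c(t_lo, t_hi, inner_bp, abs(b - L), b + L),
                              t_lo), t_hi)))
  total <- 0
  for (i in seq_len(length(bp) - 1)) {
    lo <- bp[i]; hi <- bp[i + 1]
    if (hi - lo < 1e-14) next
    tt <- lo + (hi - lo) * .gl16$x
    total <- total + (hi - lo) * sum(.gl16$w * p_t(tt) * g_t(tt))
  }
  min(max(total, 0), 1)
}

#' Cross-link data likelihood
#'
#' `p = psi * (1 - f) + f * (1 - psi)`: with probability `1 - psi` the
#' reported link reflects the model geometry (forward-model probability
#' `f`), with probability `psi` it is spurious.
#'
#' @param f forward-model probability in \[0, 1\].
#' @param psi per-class cross-link uncertainty in (0, 1).
#' @return likelihood in (0, 1).
#' @export
crosslink_likelihood <- function(f, psi) {
  stopifnot(all(f >= 0 & f <= 1), all(psi > 0 & psi < 1))
  psi * (1 - f) + f * (1 - psi)
}

#' Spectral-redundancy weight
#'
#' Links observed by many spectra are promoted: `w = min(1 + log2(n), cap)`.
#'
#' @param n_spectra spectral count (>= 1).
#' @param cap weight cap (default 4).
#' @return weight vector.
#' @export
redundancy_weight <- function(n_spectra, cap = 4) {
  pmin(1 + log2(pmax(n_spectra, 1)), cap)
}

#' Cross-link restraint score
#'
#' Negative log joint likelihood of a set of cross-links given endpoint
#' distances: `-sum_n w_n log p(d_n | sigma, psi_class(n))`, with `w_n` the
#' spectral-redundancy weight.
#'
#' @param d per-link endpoint distances (A).
#' @param n_spectra per-link spectral counts.
#' @param xl_class per-link class labels (must be names of `psi`).
#' @param sigma global positional uncertainty radius (A, > 0).
#' @param psi named vector of per-class uncertainties in (0, 1).
#' @param params a [restraint_params()] list.
#' @param details return per-link table as well.
#' @return the score, or (with `details`) a list with `score` and `links`.
#' @export
crosslink_score <- function(d, n_spectra, xl_class, sigma, psi,
                            params = restraint_params(), details = FALSE) {
  if (any(is.na(match(xl_class, names(psi)))))
    stop("xl_class labels must match names(psi)")
  f <- forward_model(d, sigma, sigma, params$l_xl)
  p <- crosslink_likelihood(f, psi[xl_class])
  w <- redundancy_weight(n_spectra, params$redundancy_cap)
  s <- -sum(w * log(p))
  if (!details) return(s)
  list(score = s, links = data.frame(d = d, f = f, p = as.numeric(p), w = w,
                                     xl_class = xl_class))
}

# log of the component-pair overlap integral
.log_overlap_pair <- function(w1, m1, S1, w2, m2, S2) {
  S <- S1 + S2
  dm <- m1 - m2
  log(w1) + log(w2) - 1.5 * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * sum(dm * solve(S, dm))
}

.gmm_log_overlap <- function(a, b) {
  terms <- numeric(0)
  for (i in seq_along(a$weights))
    for (j in seq_along(b$weights))
      terms <- c(terms, .log_overlap_pair(a$weights[i], a$means[i, ], a$covs[i, , ],
                                          b$weights[j], b$means[j, ], b$covs[j, , ]))
  mx <- max(terms)
  mx + log(sum(exp(terms - mx)))
}

#' Overlap integral of two Gaussian mixtures
#'
#' `ov(a, b) = sum_i sum_j w_i w_j N(mu_i - mu_j; 0, S_i + S_j)` — the
#' integral of the product of the two mixture densities. Symmetric in its
#' arguments.
#'
#' @param a,b [gmm()] objects.
#' @return the overlap (a positive scalar).
#' @export
gmm_overlap <- function(a, b) {
  stopifnot(inherits(a, "gmm"), inherits(b, "gmm"))
  exp(.gmm_log_overlap(a, b))
}

#' EM density restraint score
#'
#' Cross-correlation between the model and data mixtures,
#' `CC = 2 ov(M, D) / (ov(M, M) + ov(D, D))`, scored as
#' `-scale * log(CC)`. Non-negative, and exactly 0 iff the two mixtures
#' are identical as densities. Evaluated in log space so that widely
#' separated mixtures yield a large finite score rather than underflow.
#'
#' @param model_gmm,data_gmm [gmm()] objects.
#' @param scale score multiplier (default 100).
#' @return the score (>= 0).
#' @export
em_score <- function(model_gmm, data_gmm, scale = 100) {
  l_md <- .gmm_log_overlap(model_gmm, data_gmm)
  l_mm <- .gmm_log_overlap(model_gmm, model_gmm)
  l_dd <- .gmm_log_overlap(data_gmm, data_gmm)
  mx <- max(l_mm, l_dd)
  log_den <- mx + log(exp(l_mm - mx) + exp(l_dd - mx))
  log_cc <- log(2) + l_md - log_den
  -scale * log_cc
}

#' Excluded volume score
#'
#' Harmonic penalty on the overlap of bead pairs: zero when the
#' center-center distance is at least the sum of radii, `0.5 k (r1 + r2 -
#' d)^2` otherwise. Pairs within the same rigid body are exempt.
#'
#' @param beads bead data.frame (columns `x`, `y`, `z`, `radius`,
#'   `rigid_id`).
#' @param k force constant.
#' @return the score.
#' @export
excluded_volume_score <- function(beads, k = 1) {
  n <- nrow(beads)
  if (n < 2L) return(0)
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  rsum <- outer(beads$radius, beads$radius, `+`)
  same_rb <- outer(beads$rigid_id, beads$rigid_id,
                   function(a, b) !is.na(a) & !is.na(b) & a == b)
  ov <- pmax(rsum - dmat, 0)
  ov[same_rb] <- 0
  diag(ov) <- 0
  0.5 * k * sum(ov[upper.tri(ov)]^2)
}

#' Sequence connectivity score
#'
#' Harmonic upper bound on the distance between sequence-consecutive
#' beads: zero when `d <= factor * (r1 + r2)`, `0.5 k (d - thr)^2` above.
#'
#' @param beads bead data.frame.
#' @param pairs 2-column matrix of bead row indices to restrain; default:
#'   sequence-consecutive beads within each subunit that are not in the
#'   same rigid body.
#' @param factor threshold multiple of the summed radii (default 4).
#' @param k force constant.
#' @return the score.
#' @export
connectivity_score <- function(beads, pairs = NULL, factor = 4, k = 1) {
  if (is.null(pairs)) pairs <- connectivity_pairs(beads)
  if (nrow(pairs) == 0L) return(0)
  d <- sqrt((beads$x[pairs[, 1]] - beads$x[pairs[, 2]])^2 +
            (beads$y[pairs[, 1]] - beads$y[pairs[, 2]])^2 +
            (beads$z[pairs[, 1]] - beads$z[pairs[, 2]])^2)
  thr <- factor * (beads$radius[pairs[, 1]] + beads$radius[pairs[, 2]])
  0.5 * k * sum(pmax(d - thr, 0)^2)
}

#' Sequence-consecutive bead pairs needing a connectivity restraint
#' @param beads bead data.frame.
#' @return 2-column integer matrix of bead row indices.
#' @export
connectivity_pairs <- function(beads) {
  out <- matrix(integer(0), ncol = 2)
  for (su in unique(beads$subunit)) {
    idx <- which(beads$subunit == su & beads$scale != "fine")
    idx <- idx[order(beads$res_first[idx])]
    if (length(idx) < 2L) next
    for (i in seq_len(length(idx) - 1L)) {
      a <- idx[i]; b <- idx[i + 1]
      consec <- beads$res_first[b] == beads$res_last[a] + 1L
      same_rb <- !is.na(beads$rigid_id[a]) && !is.na(beads$rigid_id[b]) &&
        beads$rigid_id[a] == beads$rigid_id[b]
      if (consec && !same_rb) out <- rbind(out, c(a, b))
    }
  }
  out
}

#' Weak linear prior on cross-link distances
#' @param d cross-link endpoint distances (A).
#' @param slope score per Angstrom (default 0.01).
#' @return `slope * sum(d)`.
#' @export
linear_prior <- function(d, slope = 0.01) slope * sum(d)

#' Prior on the positional uncertainty radius
#'
#' Uniform over `[sigma_min, sigma_max]`: contributes 0 inside the
#' interval and `Inf` outside.
#'
#' @param sigma uncertainty radius (A).
#' @param sigma_min,sigma_max support bounds (default \[0, 100\]).
#' @return 0 or `Inf`.
#' @export
sigma_prior <- function(sigma, sigma_min = 0, sigma_max = 100) {
  if (sigma >= sigma_min && sigma <= sigma_max) 0 else Inf
}
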