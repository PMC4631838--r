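#' Bead radius from residue count
#'
#' The excluded volume of a bead covering `n` residues is `n * v_res`
#' (`v_res` = mean amino-acid volume, 132.9 A^3 by default, standard
#' protein density); the radius is that of the equivalent sphere,
#' `r = (3 n v_res / 4 pi)^(1/3)`. Monotone in `n`;
#' `r(8 n) = 2 r(n)`.
#'
#' @param n_residues residue count (>= 1), vectorized.
#' @param v_res mean residue volume in A^3.
#' @return radius in Angstrom.
#' @export
bead_radius <- function(n_residues, v_res = 132.9) {
  if (any(n_residues < 1)) stop("n_residues must be >= 1")
  (3 * n_residues * v_res / (4 * pi))^(1 / 3)
}

.bead_df <- function(subunit, first, last, x, y, z, scale,
                     radius = bead_radius(last - first + 1),
                     mass = 110 * (last - first + 1),
                     rigid_id = NA_integer_, mobile = TRUE) {
  data.frame(subunit = subunit, res_first = as.integer(first),
             res_last = as.integer(last),
             n_res = as.integer(last - first + 1),
             x = x, y = y, z = z, radius = radius, mass = mass,
             scale = scale, rigid_id = rigid_id, mobile = mobile,
             stringsAsFactors = FALSE)
}

#' Build fine or coarse beads from an atomic model
#'
#' Fine scale: one bead per residue, centered at the Calpha position,
#' radius from the single-residue volume. Coarse scale: consecutive
#' 10-residue segments (the terminal segment may be shorter), centered at
#' the segment's mass-weighted atomic center of mass, radius from the
#' segment volume. Segmentation starts at the first modeled residue of
#' each contiguous stretch.
#'
#' @param model an [atomic_model()].
#' @param scale `"fine"` or `"coarse"`.
#' @param chain restrict to one chain (default: all chains).
#' @param subunit subunit name recorded on the beads (default: the chain id).
#' @param segment_size residues per coarse bead (default 10).
#' @return data.frame of beads.
#' @export
build_beads <- function(model, scale = c("fine", "coarse"), chain = NULL,
                        subunit = NULL, segment_size = 10) {
  scale <- match.arg(scale)
  ca <- model$calpha
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  if (nrow(ca) == 0L) stop("empty chain")
  out <- lapply(split(ca, ca$chain), function(ch) {
    su <- if (is.null(subunit)) ch$chain[1] else subunit
    if (scale == "fine") {
      return(.bead_df(su, ch$resid, ch$resid, ch$x, ch$y, ch$z, "fine",
                      mass = ch$mass))
    }
    atoms <- model$atoms[model$atoms$chain == ch$chain[1], , drop = FALSE]
    # contiguous stretches of modeled residues
    stretch <- cumsum(c(1L, diff(ch$resid) != 1L))
    segs <- do.call(rbind, lapply(split(ch$resid, stretch), function(rr) {
      starts <- seq(1L, length(rr), by = segment_size)
      ends <- pmin(starts + segment_size - 1L, length(rr))
      data.frame(first = rr[starts], last = rr[ends])
    }))
    rows <- lapply(seq_len(nrow(segs)), function(i) {
      aa <- atoms[atoms$resid >= segs$first[i] & atoms$resid <= segs$last[i], ]
      wt <- aa$mass / sum(aa$mass)
      .bead_df(su, segs$first[i], segs$last[i],
               sum(aa$x * wt), sum(aa$y * wt), sum(aa$z * wt), "coarse",
               mass = sum(aa$mass))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a flexible string of beads for an unstructured region
#'
#' The residue range is split into contiguous segments of at most
#' `max_per_bead` residues using a near-equal deterministic rule: with
#' `n` residues and `b = ceiling(n / max_per_bead)` beads, the first
#' `n mod b` beads carry one extra residue. Each segment is represented by
#' one bead and one isotropic Gaussian sharing its center; the Gaussian
#' variance per axis is `r^2 / 5` (the per-axis variance of a uniform ball
#' of the bead radius), so the Gaussian matches the segment's molecular
#' volume.
#'
#' @param subunit subunit name.
#' @param residue_range length-2 inclusive range.
#' @param max_per_bead maximum residues per bead (default 40).
#' @param center optional common initial center (default origin; flexible
#'   beads are placed by the sampler's initialization).
#' @return list with `beads` (data.frame, scale `"flexible"`) and
#'   `gaussians` (a [gmm()] with unnormalized mass weights).
#' @export
build_flexible_string <- function(subunit, residue_range, max_per_bead = 40,
                                  center = c(0, 0, 0)) {
  r <- as.integer(residue_range)
  n <- r[2] - r[1] + 1L
  if (n < 1L) stop("zero-length residue range")
  b <- as.integer(ceiling(n / max_per_bead))
  base <- n %/% b
  extra <- n %% b
  sizes <- rep(base, b) + c(rep(1L, extra), rep(0L, b - extra))
  last <- r[1] - 1L + cumsum(sizes)
  first <- c(r[1], head(last, -1) + 1L)
  beads <- .bead_df(subunit, first, last, center[1], center[2], center[3],
                    "flexible")
  sd2 <- beads$radius^2 / 5
  covs <- array(0, dim = c(b, 3, 3))
  for (i in seq_len(b)) covs[i, , ] <- diag(rep(sd2[i], 3))
  g <- gmm(weights = beads$mass,
           means = matrix(rep(center, each = b), ncol = 3),
           covs = covs, normalize = FALSE)
  list(beads = beads, gaussians = g)
}

#' GMM representation of a structured component
#'
#' Fits `n_residues %/% 50` (minimum 1) Gaussians directly to the atomic
#' coordinates weighted by atomic mass — the atoms are the density sample.
#'
#' @param model an [atomic_model()].
#' @param chain restrict to one chain.
#' @param n_components override the component-count rule.
#' @return a [gmm()] with weights rescaled to the total mass.
#' @export
gmm_from_structure <- function(model, chain = NULL, n_components = NULL) {
  at <- model$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain")
  n_res <- length(unique(paste(at$chain, at$resid)))
  k <- if (is.null(n_components)) n_gaussians_for(n_res) else n_components
  g <- fit_gmm(cbind(at$x, at$y, at$z), at$mass, k)
  scale_gmm_mass(g, sum(at$mass))
}
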