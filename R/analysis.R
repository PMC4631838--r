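#' Beads and weights used for ensemble RMSD
#'
#' The RMSD between solutions is computed on the primary representation of
#' every residue: fine (per-residue) beads for structured regions, coarse
#' beads for flexible strings; the weight of a bead is the number of
#' residues it represents.
#'
#' @param system an [assembly_system()].
#' @return list with `idx` (bead row indices) and `w` (residue counts).
#' @export
rmsd_beads <- function(system) {
  b <- system$beads
  keep <- logical(nrow(b))
  for (su in unique(b$subunit)) {
    sel <- b$subunit == su
    fine_res <- unlist(Map(seq, b$res_first[sel & b$scale == "fine"],
                           b$res_last[sel & b$scale == "fine"]))
    keep[sel & b$scale == "fine"] <- TRUE
    other <- which(sel & b$scale != "fine")
    for (i in other)
      if (!any(seq(b$res_first[i], b$res_last[i]) %in% fine_res))
        keep[i] <- TRUE
  }
  list(idx = which(keep), w = b$n_res[keep])
}

#' Size-weighted RMSD between two frames
#'
#' `RMSD = sqrt( sum_b n_b |x_b,a - x_b,b|^2 / sum_b n_b )`, with `n_b` the
#' number of residues represented by bead `b`. No superposition is applied:
#' the density restraint fixes the global frame.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices over the same beads.
#' @param weights per-bead residue counts (default 1).
#' @return RMSD in Angstrom.
#' @export
weighted_rmsd <- function(coords_a, coords_b, weights = NULL) {
  coords_a <- matrix(as.numeric(coords_a), ncol = 3)
  coords_b <- matrix(as.numeric(coords_b), ncol = 3)
  if (nrow(coords_a) != nrow(coords_b)) stop("mismatched bead lists")
  if (is.null(weights)) weights <- rep(1, nrow(coords_a))
  sq <- rowSums((coords_a - coords_b)^2)
  sqrt(sum(weights * sq) / sum(weights))
}

#' Collect frames from trajectories
#' @param trajectories list of trajectories from [run_replica_exchange()].
#' @return list with `coords` (beads x 3 x frames), `score`, `run`,
#'   `sigma`, `psi` per frame.
#' @export
gather_frames <- function(trajectories) {
  nb <- dim(trajectories[[1]]$frames)[1]
  nf <- sum(vapply(trajectories, function(t) dim(t$frames)[3], integer(1)))
  coords <- array(0, dim = c(nb, 3, nf))
  score <- numeric(nf); run <- integer(nf); sigma <- numeric(nf)
  psi <- matrix(0, nf, 2, dimnames = list(NULL, c("intra_module", "inter_module")))
  k <- 0
  for (t in trajectories) {
    m <- dim(t$frames)[3]
    coords[, , k + seq_len(m)] <- t$frames
    score[k + seq_len(m)] <- t$scores$total
    run[k + seq_len(m)] <- t$run
    sigma[k + seq_len(m)] <- t$sigma
    psi[k + seq_len(m), ] <- t$psi
    k <- k + m
  }
  list(coords = coords, score = score, run = run, sigma = sigma, psi = psi)
}

#' Select best-scoring solutions and cluster them by weighted RMSD
#'
#' Takes the `n_best` lowest-scoring frames across all runs, computes the
#' pairwise size-weighted RMSD matrix, and partitions it with k-medoids
#' (PAM) — the cluster center (medoid) is the solution with the minimal
#' summed RMSD to the other members, and the cluster precision is the
#' average RMSD of members to the center.
#'
#' @param trajectories list of trajectories.
#' @param system the [assembly_system()].
#' @param n_best number of best-scoring models to keep (default 500).
#' @param k number of clusters.
#' @return object of class `cluster_ensemble`: `coords` (selected frames),
#'   `score`, `run`, `sigma`, `psi`, `rmsd` (matrix), `assignment`,
#'   `centers` (frame index per cluster), `precision` (per cluster, A),
#'   `population`, `between_rmsd` (k x k average-linkage matrix).
#' @export
select_and_cluster <- function(trajectories, system, n_best = 500, k = 1) {
  fr <- gather_frames(trajectories)
  nf <- length(fr$score)
  if (nf < n_best) stop("only ", nf, " frames available, need n_best = ", n_best)
  if (k > n_best) stop("k cannot exceed n_best")
  sel <- order(fr$score)[seq_len(n_best)]
  rb <- rmsd_beads(system)
  co <- fr$coords[rb$idx, , sel, drop = FALSE]
  rmsd <- rmsd_matrix(co, rb$w)
  if (k == 1L) {
    assign <- rep(1L, n_best)
    centers <- which.min(rowSums(rmsd))
  } else {
    pam <- cluster::pam(stats::as.dist(rmsd), k = k, diss = TRUE)
    assign <- as.integer(pam$clustering)
    centers <- as.integer(pam$id.med)
  }
  # order clusters by mean score (best first): the top cluster is the one
  # with the best average score, ties broken by population
  pop <- tabulate(assign, k)
  mean_sc <- vapply(seq_len(k), function(cl) mean(fr$score[sel][assign == cl]),
                    numeric(1))
  ord <- order(mean_sc, -pop)
  relabel <- match(seq_len(k), ord)
  assign <- relabel[assign]
  centers <- centers[ord]
  pop <- pop[ord]
  precision <- vapply(seq_len(k), function(cl) {
    mem <- which(assign == cl)
    mean(rmsd[mem, centers[cl]])
  }, numeric(1))
  between <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) between[i, j] <- mean(rmsd[assign == i, assign == j])
  structure(list(coords = fr$coords[, , sel, drop = FALSE],
                 score = fr$score[sel], run = fr$run[sel],
                 sigma = fr$sigma[sel], psi = fr$psi[sel, , drop = FALSE],
                 rmsd = rmsd, assignment = assign, centers = centers,
                 precision = precision, population = pop,
                 between_rmsd = between, rmsd_idx = rb$idx, rmsd_w = rb$w),
            class = "cluster_ensemble")
}

#' Pairwise size-weighted RMSD matrix
#' @param coords beads x 3 x frames array (already restricted to RMSD beads).
#' @param weights per-bead residue counts.
#' @return symmetric matrix with zero diagonal.
#' @export
rmsd_matrix <- function(coords, weights) {
  n <- dim(coords)[3]
  flat <- matrix(coords, nrow = dim(coords)[1] * 3, ncol = n)
  w3 <- rep(weights, 3)
  wsum <- sum(weights)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d2 <- colSums(w3 * (flat[, (i + 1):n, drop = FALSE] - flat[, i])^2) / wsum
    out[i, (i + 1):n] <- out[(i + 1):n, i] <- sqrt(pmax(d2, 0))
  }
  out
}

#' Per-bead root-mean-square fluctuation within a cluster
#'
#' RMSF of a residue is the spread of distances between its bead position
#' in each cluster member and its position in the cluster center:
#' `sqrt(mean(d_i^2))` over members.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param system the [assembly_system()].
#' @param cluster cluster label (default 1, the most populated).
#' @return data.frame of beads with an `rmsf` column (A).
#' @export
rmsf <- function(ensemble, system, cluster = 1) {
  mem <- which(ensemble$assignment == cluster)
  ctr <- ensemble$centers[cluster]
  co <- ensemble$coords[, , mem, drop = FALSE]
  cc <- ensemble$coords[, , ctr]
  d2 <- apply(co, 3, function(f) rowSums((f - cc)^2))
  out <- system$beads[, c("subunit", "res_first", "res_last", "n_res", "scale")]
  out$rmsf <- sqrt(rowMeans(matrix(d2, nrow = nrow(out))))
  out
}

#' Precision of a subunit or module selection
#'
#' Average size-weighted RMSD between cluster members and the cluster
#' center, restricted to the beads of a selection.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param system the [assembly_system()].
#' @param subunits subunit names to include (default all).
#' @param cluster cluster label.
#' @return precision in Angstrom.
#' @export
subunit_precision <- function(ensemble, system, subunits = NULL, cluster = 1) {
  rb <- rmsd_beads(system)
  keep <- if (is.null(subunits)) rep(TRUE, length(rb$idx))
          else system$beads$subunit[rb$idx] %in% subunits
  if (!any(keep)) stop("unknown selection")
  mem <- which(ensemble$assignment == cluster)
  ctr <- ensemble$centers[cluster]
  idx <- rb$idx[keep]; w <- rb$w[keep]
  mean(vapply(mem, function(i)
    weighted_rmsd(ensemble$coords[idx, , i], ensemble$coords[idx, , ctr], w),
    numeric(1)))
}

#' Localization probability density of a subunit
#'
#' For each voxel, the fraction of cluster members in which any bead of
#' the subunit (as a hard sphere of its radius) covers the voxel center.
#' Values are probabilities in \[0, 1\]; the conventional display
#' threshold is 0.15.
#'
#' @param ensemble a `cluster_ensemble` (or a beads x 3 x frames array).
#' @param system the [assembly_system()].
#' @param subunit subunit name.
#' @param origin,spacing,dims grid; defaults derived from the frames with
#'   10 A padding and 4 A spacing.
#' @param cluster cluster label (ignored when `ensemble` is an array).
#' @return a [voxel_map()] with `threshold = 0.15`.
#' @export
localization_density <- function(ensemble, system, subunit, origin = NULL,
                                 spacing = 4, dims = NULL, cluster = 1) {
  if (is.array(ensemble)) {
    co <- ensemble
  } else {
    mem <- which(ensemble$assignment == cluster)
    if (!length(mem)) stop("empty cluster")
    co <- ensemble$coords[, , mem, drop = FALSE]
  }
  sel <- which(system$beads$subunit == subunit & system$beads$scale != "fine")
  if (!length(sel)) sel <- which(system$beads$subunit == subunit)
  if (!length(sel)) stop("unknown subunit: ", subunit)
  rad <- system$beads$radius[sel]
  if (is.null(origin) || is.null(dims)) {
    pts <- matrix(aperm(co[sel, , , drop = FALSE], c(1, 3, 2)), ncol = 3)
    lo <- apply(pts, 2, min) - 10
    hi <- apply(pts, 2, max) + 10
    origin <- lo
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  map <- voxel_map(array(0, dim = dims), origin = origin, spacing = spacing,
                   threshold = 0.15)
  ctr <- voxel_centers(map)
  occ <- numeric(nrow(ctr))
  nf <- dim(co)[3]
  for (fidx in seq_len(nf)) {
    inside <- rep(FALSE, nrow(ctr))
    for (j in seq_along(sel)) {
      d2 <- (ctr[, 1] - co[sel[j], 1, fidx])^2 +
            (ctr[, 2] - co[sel[j], 2, fidx])^2 +
            (ctr[, 3] - co[sel[j], 3, fidx])^2
      inside <- inside | d2 <= rad[j]^2
    }
    occ <- occ + inside
  }
  map$data <- array(occ / nf, dim = dims)
  map
}

#' Residue- and domain-level contact frequency maps
#'
#' Two beads are in contact when their surface distance (center distance
#' minus both radii) is below `cutoff` (10 A). The bead-pair frequency is
#' the fraction of cluster members with the contact formed; the domain map
#' aggregates beads into `domain_size`-residue blocks (200 by default)
#' taking the maximum bead-pair frequency within each block pair.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param system the [assembly_system()].
#' @param cutoff surface distance cutoff in Angstrom.
#' @param domain_size residues per domain block.
#' @param cluster cluster label.
#' @return list with `bead_freq` (matrix over RMSD beads), `beads`
#'   (their metadata), `domain_freq`, `domains` (block metadata).
#' @export
contact_maps <- function(ensemble, system, cutoff = 10, domain_size = 200,
                         cluster = 1) {
  mem <- which(ensemble$assignment == cluster)
  rb <- rmsd_beads(system)
  b <- system$beads[rb$idx, ]
  n <- length(rb$idx)
  freq <- matrix(0, n, n)
  rsum <- outer(b$radius, b$radius, `+`)
  for (i in mem) {
    co <- ensemble$coords[rb$idx, , i]
    dmat <- as.matrix(stats::dist(co))
    freq <- freq + (dmat - rsum < cutoff)
  }
  freq <- freq / length(mem)
  diag(freq) <- 1
  dom <- paste(b$subunit, (b$res_first - 1L) %/% domain_size)
  doms <- unique(dom)
  dfreq <- matrix(0, length(doms), length(doms),
                  dimnames = list(doms, doms))
  for (i in seq_along(doms)) for (j in seq_along(doms)) {
    dfreq[i, j] <- max(freq[dom == doms[i], dom == doms[j]])
  }
  list(bead_freq = freq, beads = b, domain_freq = dfreq,
       domains = data.frame(domain = doms,
                            subunit = b$subunit[match(doms, dom)]))
}

#' Cross-link satisfaction statistics for a cluster
#'
#' Per-link endpoint distances evaluated on the cluster center and, for
#' reference, the minimum over all cluster members; a link is satisfied
#' when its distance is at or below `threshold`. Fractions are reported
#' separately per cross-link class.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param system the [assembly_system()] (must carry cross-links).
#' @param threshold satisfaction threshold in Angstrom (35 by default,
#'   the conventional Calpha violation distance; use the linker length
#'   for generation-cutoff checks).
#' @param cluster cluster label.
#' @return list with `links` (distances and flags) and `by_class`
#'   (satisfied fractions on the center and by cluster minimum).
#' @export
satisfaction_stats <- function(ensemble, system, threshold = 35, cluster = 1) {
  xl <- system$crosslinks
  if (is.null(xl)) stop("system has no cross-links")
  mem <- which(ensemble$assignment == cluster)
  ctr <- ensemble$centers[cluster]
  dist_on <- function(i) {
    co <- ensemble$coords[, , i]
    sqrt(rowSums((co[xl$bead1, , drop = FALSE] - co[xl$bead2, , drop = FALSE])^2))
  }
  d_center <- dist_on(ctr)
  d_min <- do.call(pmin, lapply(mem, dist_on))
  links <- data.frame(xl[, c("protein1", "residue1", "protein2", "residue2",
                             "n_spectra", "xl_class")],
                      d_center = d_center, d_min = d_min,
                      satisfied_center = d_center <= threshold,
                      satisfied_min = d_min <= threshold)
  by_class <- do.call(rbind, lapply(split(links, links$xl_class), function(g)
    data.frame(xl_class = g$xl_class[1], n = nrow(g),
               satisfied_center = mean(g$satisfied_center),
               satisfied_min = mean(g$satisfied_min))))
  rownames(by_class) <- NULL
  list(links = links, by_class = by_class, threshold = threshold)
}

#' Voxelwise cross-correlation of two density maps on a common grid
#' @param a,b [voxel_map()] objects with identical grids.
#' @return `2*sum(ab) / (sum(a^2) + sum(b^2))`, in \[0, 1\] and 1 iff
#'   identical.
#' @export
map_cc <- function(a, b) {
  stopifnot(all(dim(a$data) == dim(b$data)))
  den <- sum(a$data^2) + sum(b$data^2)
  if (den == 0) return(NA_real_)
  2 * sum(a$data * b$data) / den
}

#' Sampling exhaustiveness check
#'
#' Splits the runs into halves, selects the best-scoring models from each
#' half independently, and compares per-subunit localization densities
#' (voxelwise cross-correlation on a common grid) and precisions. High
#' half-vs-half CC indicates the sampling has converged on the same set
#' of solutions.
#'
#' @param trajectories list of >= 2 trajectories.
#' @param system the [assembly_system()].
#' @param n_best best-scoring models per half.
#' @param spacing localization grid spacing (A).
#' @return list with per-subunit `density_cc`, per-half `precision`, and
#'   the half memberships.
#' @export
exhaustiveness_check <- function(trajectories, system, n_best = 100,
                                 spacing = 4) {
  nr <- length(trajectories)
  if (nr < 2) stop("need at least 2 runs")
  half1 <- trajectories[seq_len(nr %/% 2)]
  half2 <- trajectories[(nr %/% 2 + 1):nr]
  sel_coords <- function(half) {
    fr <- gather_frames(half)
    nb <- min(n_best, length(fr$score))
    fr$coords[, , order(fr$score)[seq_len(nb)], drop = FALSE]
  }
  co1 <- sel_coords(half1)
  co2 <- sel_coords(half2)
  # common grid over both halves
  pts <- rbind(matrix(aperm(co1, c(1, 3, 2)), ncol = 3),
               matrix(aperm(co2, c(1, 3, 2)), ncol = 3))
  lo <- apply(pts, 2, min) - 10
  hi <- apply(pts, 2, max) + 10
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  subs <- unique(system$beads$subunit)
  cc <- vapply(subs, function(su) {
    m1 <- localization_density(co1, system, su, origin = lo,
                               spacing = spacing, dims = dims)
    m2 <- localization_density(co2, system, su, origin = lo,
                               spacing = spacing, dims = dims)
    map_cc(m1, m2)
  }, numeric(1))
  names(cc) <- subs
  prec <- vapply(list(co1, co2), function(co) {
    rb <- rmsd_beads(system)
    x <- co[rb$idx, , , drop = FALSE]
    rm <- rmsd_matrix(x, rb$w)
    ctr <- which.min(rowSums(rm))
    mean(rm[, ctr])
  }, numeric(1))
  list(density_cc = cc, precision = c(half1 = prec[1], half2 = prec[2]),
       n_half = c(length(half1), length(half2)))
}

#' Segment a density map among modules
#'
#' Subtracts the rasterized density of the fixed (docked) component, then
#' partitions the remaining above-threshold voxels between two modules so
#' that their volumes are proportional to the module masses. Voxels are
#' assigned by a biased nearest-seed rule (seeds are the two mutually
#' farthest remainder voxels); the bias is found by monotone bisection on
#' the volume ratio.
#'
#' @param map a [voxel_map()].
#' @param fixed_gmm [gmm()] of the docked component (mass weights), or
#'   NULL to skip subtraction.
#' @param module_masses named numeric length-2: target masses.
#' @param threshold density threshold defining occupied voxels.
#' @return named list of two [voxel_map()]s (density restricted to each
#'   module's region).
#' @export
segment_density <- function(map, fixed_gmm, module_masses, threshold = 0) {
  stopifnot(length(module_masses) == 2, all(module_masses >= 0))
  rem <- map$data
  if (!is.null(fixed_gmm)) {
    fx <- rasterize_gmm(fixed_gmm, origin = map$origin, spacing = map$spacing,
                        dims = dim(map$data))
    # scale the subtracted density so its integral matches the component's
    # share of the map (weights are masses, map units arbitrary)
    tot_map <- sum(map$data[map$data > threshold])
    tot_mass <- sum(fixed_gmm$weights) + sum(module_masses)
    fac <- tot_map * sum(fixed_gmm$weights) / tot_mass / max(sum(fx$data), 1e-300)
    rem <- pmax(rem - fx$data * fac / 1, 0)
    rem <- array(rem, dim = dim(map$data))
  }
  occ <- which(rem > threshold)
  if (length(occ) < 2) stop("remainder volume too small to segment")
  ctr <- voxel_centers(map)[occ, , drop = FALSE]
  if (module_masses[2] == 0) {
    m1 <- map; m1$data <- array(ifelse(seq_along(rem) %in% occ, rem, 0), dim(rem))
    m2 <- map; m2$data <- array(0, dim(rem))
    out <- list(m1, m2)
    names(out) <- names(module_masses)
    return(out)
  }
  # seeds: approximately mutually farthest voxels
  com <- colMeans(ctr)
  s1 <- which.max(rowSums(sweep(ctr, 2, com)^2))
  s2 <- which.max(rowSums(sweep(ctr, 2, ctr[s1, ])^2))
  d1 <- sqrt(rowSums(sweep(ctr, 2, ctr[s1, ])^2))
  d2 <- sqrt(rowSums(sweep(ctr, 2, ctr[s2, ])^2))
  target1 <- module_masses[1] / sum(module_masses)
  # assign to module 1 iff d1 - d2 < c; c monotone in the module-1 volume.
  # Both anchorings (module 1 on seed 1 or on seed 2) give the right volume
  # split; keep the one whose density mass aligns better with the module
  # masses.
  partition <- function(tgt) {
    f <- function(cc) mean(d1 - d2 < cc) - tgt
    lo <- min(d1 - d2) - 1; hi <- max(d1 - d2) + 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    d1 - d2 < (lo + hi) / 2
  }
  cand1 <- partition(target1)       # module 1 around seed 1
  cand2 <- !partition(1 - target1)  # module 1 around seed 2
  mass_share <- function(sel) sum(rem[occ[sel]]) / sum(rem[occ])
  in1 <- if (abs(mass_share(cand1) - target1) <=
             abs(mass_share(cand2) - target1)) cand1 else cand2
  mk <- function(sel) {
    dat <- array(0, dim(rem))
    dat[occ[sel]] <- rem[occ[sel]]
    m <- map; m$data <- dat; m
  }
  out <- list(mk(in1), mk(!in1))
  names(out) <- if (!is.null(names(module_masses))) names(module_masses)
                else c("module1", "module2")
  out
}
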