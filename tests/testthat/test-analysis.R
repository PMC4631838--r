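test_that("weighted RMSD matches hand arithmetic and brute force", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(weighted_rmsd(a, b), 0)
  b2 <- rbind(c(5, 0, 0), c(1, 0, 0))
  expect_equal(weighted_rmsd(a[1, , drop = FALSE], b2[1, , drop = FALSE]), 5)
  # beads with n = (1, 3), displacements (2, 0) -> sqrt(4/4) = 1
  b3 <- rbind(c(2, 0, 0), c(1, 0, 0))
  expect_equal(weighted_rmsd(a, b3, weights = c(1, 3)), 1)
  # brute force on random frames
  set.seed(300)
  for (i in 1:5) {
    n <- 17
    x <- matrix(rnorm(3 * n), ncol = 3)
    y <- matrix(rnorm(3 * n), ncol = 3)
    w <- sample(1:10, n, TRUE)
    ref <- sqrt(sum(w * rowSums((x - y)^2)) / sum(w))
    expect_equal(weighted_rmsd(x, y, w), ref, tolerance = 1e-12)
  }
  expect_error(weighted_rmsd(a, a[1, , drop = FALSE]), "mismatched")
})

test_that("weighted RMSD is a pseudo-metric on random frames", {
  set.seed(301)
  n <- 10
  w <- sample(1:5, n, TRUE)
  fr <- replicate(4, matrix(rnorm(3 * n, sd = 5), ncol = 3), simplify = FALSE)
  for (i in 1:4) for (j in 1:4) {
    dij <- weighted_rmsd(fr[[i]], fr[[j]], w)
    expect_equal(dij, weighted_rmsd(fr[[j]], fr[[i]], w))
    if (i == j) expect_equal(dij, 0)
    for (k in 1:4)
      expect_lte(dij, weighted_rmsd(fr[[i]], fr[[k]], w) +
                      weighted_rmsd(fr[[k]], fr[[j]], w) + 1e-12)
  }
})

# build a fake ensemble of frames around two planted conformations
planted_trajectories <- function(sys, n_frames = 30, sep = 60, jitter = 0.5,
                                 scores = NULL) {
  nb <- nrow(sys$beads)
  base <- as.matrix(sys$beads[, c("x", "y", "z")])
  shift <- matrix(0, nb, 3)
  shift[sys$beads$mobile, 1] <- sep
  frames <- array(0, dim = c(nb, 3, n_frames))
  lab <- rep(1:2, length.out = n_frames)
  for (i in seq_len(n_frames)) {
    f <- base + if (lab[i] == 2) shift else 0
    f <- f + matrix(rnorm(3 * nb, sd = jitter), nb, 3)
    f[!sys$beads$mobile, ] <- base[!sys$beads$mobile, ]
    frames[, , i] <- f
  }
  if (is.null(scores)) scores <- seq_len(n_frames)
  list(list(frames = frames,
            scores = data.frame(total = scores),
            sigma = rep(1, n_frames),
            psi = matrix(0.05, n_frames, 2,
                         dimnames = list(NULL, c("intra_module", "inter_module"))),
            gmeans = vector("list", n_frames), gcovs = vector("list", n_frames),
            swap_rate = NA, run = 1L),
       truth_labels = lab)
}

test_that("clustering separates planted conformations perfectly", {
  sys <- small_system()
  pt <- planted_trajectories(sys, n_frames = 30)
  ens <- select_and_cluster(pt[1], sys, n_best = 30, k = 2)
  lab <- pt$truth_labels
  # adjusted-Rand-1 partition: assignments must match labels up to renaming
  tab <- table(ens$assignment, lab)
  expect_equal(unname(sort(colSums(tab != 0))), c(1, 1))
  expect_true(all(ens$precision < 2))
  expect_gt(ens$between_rmsd[1, 2], 20)
  # all identical frames, k = 1: precision exactly 0
  pt0 <- planted_trajectories(sys, n_frames = 10, sep = 0, jitter = 0)
  ens0 <- select_and_cluster(pt0[1], sys, n_best = 10, k = 1)
  expect_equal(ens0$precision, 0)
  expect_error(select_and_cluster(pt0[1], sys, n_best = 50, k = 1), "frames")
  expect_error(select_and_cluster(pt0[1], sys, n_best = 10, k = 11), "exceed")
})

test_that("cluster centers match the exhaustive argmin of summed RMSD", {
  sys <- small_system()
  set.seed(302)
  pt <- planted_trajectories(sys, n_frames = 18, sep = 0, jitter = 3)
  ens <- select_and_cluster(pt[1], sys, n_best = 18, k = 1)
  sums <- rowSums(ens$rmsd)
  expect_equal(ens$centers[1], which.min(sums))
  # invariance to frame order: permute scores so selection order changes
  pt2 <- pt
  perm <- sample(18)
  pt2[[1]]$frames <- pt[[1]]$frames[, , perm]
  pt2[[1]]$scores <- data.frame(total = pt[[1]]$scores$total[perm])
  pt2[[1]]$sigma <- pt[[1]]$sigma[perm]
  pt2[[1]]$psi <- pt[[1]]$psi[perm, ]
  ens2 <- select_and_cluster(pt2[1], sys, n_best = 18, k = 1)
  expect_equal(ens2$precision, ens$precision, tolerance = 1e-9)
})

test_that("RMSF is zero for fixed beads and matches hand computation", {
  sys <- small_system()
  pt <- planted_trajectories(sys, n_frames = 12, sep = 0, jitter = 1)
  ens <- select_and_cluster(pt[1], sys, n_best = 12, k = 1)
  r <- rmsf(ens, sys)
  fixed <- !sys$beads$mobile
  expect_true(all(r$rmsf[fixed] == 0))
  expect_true(all(r$rmsf[!fixed] > 0))
  # hand-computed: 3-frame cluster, single bead displaced along x
  mem <- which(ens$assignment == 1)
  ctr <- ens$centers[1]
  i <- which(sys$beads$mobile)[1]
  d <- sqrt(colSums((ens$coords[i, , mem] - ens$coords[i, , ctr])^2))
  expect_equal(r$rmsf[i], sqrt(mean(d^2)), tolerance = 1e-9)
  # single-frame cluster: RMSF 0 everywhere
  pt1 <- planted_trajectories(sys, n_frames = 1, sep = 0, jitter = 1)
  ens1 <- select_and_cluster(pt1[1], sys, n_best = 1, k = 1)
  expect_true(all(rmsf(ens1, sys)$rmsf == 0))
})

test_that("subunit precision restricts to the selection", {
  sys <- small_system()
  pt <- planted_trajectories(sys, n_frames = 10, sep = 0, jitter = 1)
  ens <- select_and_cluster(pt[1], sys, n_best = 10, k = 1)
  su_fixed <- unique(sys$beads$subunit[!sys$beads$mobile])
  expect_equal(subunit_precision(ens, sys, subunits = su_fixed), 0)
  expect_gt(subunit_precision(ens, sys), 0)
  expect_error(subunit_precision(ens, sys, subunits = "nope"), "selection")
})

test_that("localization densities are occupancy probabilities", {
  sys <- small_system()
  # two frames with disjoint placements of a mobile subunit
  pt <- planted_trajectories(sys, n_frames = 2, sep = 80, jitter = 0)
  ens <- select_and_cluster(pt[1], sys, n_best = 2, k = 1)
  su <- unique(sys$beads$subunit[sys$beads$mobile])[1]
  m <- localization_density(ens, sys, su, spacing = 3)
  expect_true(all(m$data >= 0 & m$data <= 1))
  expect_equal(sort(unique(as.numeric(m$data))), c(0, 0.5))
  expect_equal(m$threshold, 0.15)
  # fixed subunit: binary occupancy
  suf <- unique(sys$beads$subunit[!sys$beads$mobile])[1]
  mf <- localization_density(ens, sys, suf, spacing = 3)
  expect_setequal(unique(as.numeric(mf$data)), c(0, 1))
  # single frame: binary
  pt1 <- planted_trajectories(sys, n_frames = 1, sep = 0, jitter = 0)
  ens1 <- select_and_cluster(pt1[1], sys, n_best = 1, k = 1)
  m1 <- localization_density(ens1, sys, su, spacing = 3)
  expect_setequal(unique(as.numeric(m1$data)), c(0, 1))
})

test_that("contact maps follow the surface-distance rule and a naive oracle", {
  sys <- small_system()
  set.seed(303)
  pt <- planted_trajectories(sys, n_frames = 5, sep = 0, jitter = 2)
  ens <- select_and_cluster(pt[1], sys, n_best = 5, k = 1)
  cm <- contact_maps(ens, sys, cutoff = 10)
  rb <- rmsd_beads(sys)
  b <- sys$beads[rb$idx, ]
  # naive double loop over frames and pairs
  ref <- matrix(0, nrow(b), nrow(b))
  for (f in 1:5) {
    co <- ens$coords[rb$idx, , f]
    for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (d - b$radius[i] - b$radius[j] < 10) ref[i, j] <- ref[i, j] + 0.2
    }
  }
  expect_equal(cm$bead_freq, ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(cm$domain_freq >= 0 & cm$domain_freq <= 1))
  # threshold rule: radius 3+3 beads at 15 -> contact, at 17 -> none
  expect_true(15 - 6 < 10)
  expect_false(17 - 6 < 10)
})

test_that("satisfaction fractions match hand counts and are monotone", {
  sys <- small_system()
  pt <- planted_trajectories(sys, n_frames = 4, sep = 0, jitter = 0.3)
  ens <- select_and_cluster(pt[1], sys, n_best = 4, k = 1)
  st <- satisfaction_stats(ens, sys, threshold = 21)
  xl <- sys$crosslinks
  ctr <- ens$coords[, , ens$centers[1]]
  d_ref <- sqrt(rowSums((ctr[xl$bead1, ] - ctr[xl$bead2, ])^2))
  expect_equal(st$links$d_center, d_ref, tolerance = 1e-12)
  expect_equal(mean(st$links$satisfied_center[st$links$xl_class == "intra_module"]),
               st$by_class$satisfied_center[st$by_class$xl_class == "intra_module"])
  # monotone in threshold
  f1 <- mean(satisfaction_stats(ens, sys, threshold = 15)$links$satisfied_center)
  f2 <- mean(satisfaction_stats(ens, sys, threshold = 25)$links$satisfied_center)
  f3 <- mean(satisfaction_stats(ens, sys, threshold = 35)$links$satisfied_center)
  expect_true(f1 <= f2 && f2 <= f3)
  expect_true(all(st$links$d_min <= st$links$d_center + 1e-12))
})

test_that("identical run halves give density CC of 1 per subunit", {
  sys <- small_system()
  pt1 <- planted_trajectories(sys, n_frames = 10, sep = 0, jitter = 1)[[1]]
  pt2 <- pt1
  pt2$run <- 2L
  ex <- exhaustiveness_check(list(pt1, pt2), sys, n_best = 10)
  expect_true(all(abs(ex$density_cc - 1) < 1e-12))
  expect_equal(unname(ex$precision[1]), unname(ex$precision[2]))
  expect_error(exhaustiveness_check(list(pt1), sys), "2 runs")
})

test_that("density segmentation apportions volume by mass", {
  # dumbbell map: two separated blobs rasterized from a known mixture
  covs <- array(0, dim = c(2, 3, 3))
  covs[1, , ] <- diag(3) * 25
  covs[2, , ] <- diag(3) * 25
  g <- gmm(c(2, 1), rbind(c(-25, 0, 0), c(25, 0, 0)), covs,
           normalize = FALSE)
  map <- rasterize_gmm(g, spacing = 2.5, pad = 12)
  segs <- segment_density(map, NULL, c(A = 2, B = 1),
                          threshold = max(map$data) / 60)
  vol <- vapply(segs, function(m) sum(m$data > 0), numeric(1))
  expect_equal(unname(vol[1] / sum(vol)), 2 / 3, tolerance = 0.02)
  # the heavy region sits on the heavy lobe
  ctrA <- colSums(voxel_centers(segs$A) * as.numeric(segs$A$data)) /
    sum(segs$A$data)
  expect_lt(ctrA[1], 0)
  # equal masses -> equal volumes within a voxel-shell tolerance
  segs2 <- segment_density(map, NULL, c(A = 1, B = 1),
                           threshold = max(map$data) / 60)
  vol2 <- vapply(segs2, function(m) sum(m$data > 0), numeric(1))
  expect_equal(unname(vol2[1] / sum(vol2)), 0.5, tolerance = 0.02)
  # zero-mass second module -> everything in the first
  segs3 <- segment_density(map, NULL, c(A = 1, B = 0),
                           threshold = max(map$data) / 60)
  expect_equal(sum(segs3$B$data), 0)
  expect_gt(sum(segs3$A$data), 0)
})

test_that("segmentation subtracts a docked fixed component first", {
  covs <- array(0, dim = c(3, 3, 3))
  for (i in 1:3) covs[i, , ] <- diag(3) * 25
  g_all <- gmm(c(1, 1, 1), rbind(c(-30, 0, 0), c(0, 0, 0), c(30, 0, 0)),
               covs, normalize = FALSE)
  map <- rasterize_gmm(g_all, spacing = 2.5, pad = 12)
  fixed <- gmm(1, matrix(c(0, 0, 0), 1, 3),
               array(diag(3) * 25, dim = c(1, 3, 3)), normalize = FALSE)
  segs <- segment_density(map, fixed, c(left = 1, right = 1),
                          threshold = max(map$data) / 60)
  ctrL <- colSums(voxel_centers(segs$left) * as.numeric(segs$left$data)) /
    sum(segs$left$data)
  ctrR <- colSums(voxel_centers(segs$right) * as.numeric(segs$right$data)) /
    sum(segs$right$data)
  expect_equal(unname(sort(c(ctrL[1], ctrR[1]))), c(-30, 30), tolerance = 6)
})
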