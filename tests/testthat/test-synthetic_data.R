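test_that("toy assemblies realize the contact graph deterministically", {
  set.seed(400)
  spec <- toy_assembly_spec(n_subunits = 4)
  toy <- make_toy_assembly(spec)
  # same seed -> identical assembly
  set.seed(400)
  toy2 <- make_toy_assembly(spec)
  expect_identical(toy$truth, toy2$truth)
  # declared contacts at coarse-bead surface distance < 10 A, others apart
  coarse <- toy$beads[toy$beads$scale == "coarse", ]
  surf <- function(s1, s2) {
    b1 <- coarse[coarse$subunit == s1, ]
    b2 <- coarse[coarse$subunit == s2, ]
    min(outer(seq_len(nrow(b1)), seq_len(nrow(b2)), Vectorize(function(i, j)
      sqrt(sum((unlist(b1[i, c("x", "y", "z")]) -
                unlist(b2[j, c("x", "y", "z")]))^2)) -
        b1$radius[i] - b2$radius[j])))
  }
  su <- LETTERS[1:4]
  is_contact <- matrix(FALSE, 4, 4)
  for (e in seq_len(nrow(spec$contacts)))
    is_contact[spec$contacts[e, 1], spec$contacts[e, 2]] <-
      is_contact[spec$contacts[e, 2], spec$contacts[e, 1]] <- TRUE
  for (i in 1:3) for (j in (i + 1):4) {
    if (is_contact[i, j]) expect_lt(surf(su[i], su[j]), 10)
  }
  # single subunit: no excluded-volume violations within the chain beads
  set.seed(401)
  toy1 <- make_toy_assembly(toy_assembly_spec(n_subunits = 1, lengths = 10))
  coarse1 <- toy1$beads[toy1$beads$scale == "coarse", ]
  expect_equal(excluded_volume_score(coarse1), 0)
  expect_error(toy_assembly_spec(n_subunits = 4,
                                 contacts = rbind(c(1, 2), c(3, 4))),
               "connected")
})

test_that("every residue is covered once per scale and PDB files round-trip", {
  toy <- small_toy()
  for (su in names(toy$truth)) {
    n <- nrow(toy$truth[[su]])
    fine <- toy$beads[toy$beads$subunit == su & toy$beads$scale == "fine", ]
    coarse <- toy$beads[toy$beads$subunit == su & toy$beads$scale == "coarse", ]
    expect_equal(sort(fine$res_first), 1:n)
    expect_equal(sum(coarse$n_res), n)
    expect_equal(unlist(Map(seq, coarse$res_first, coarse$res_last),
                        use.names = FALSE), 1:n)
  }
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$models[[1]], p)
  back <- read_structure(p)
  expect_equal(as.matrix(back$calpha[, c("x", "y", "z")]),
               toy$truth[[1]], tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("simulated cross-links respect the cutoff and noise arithmetic", {
  toy <- small_toy()
  set.seed(402)
  xl0 <- simulate_crosslinks(toy, n_true = 20, noise_fraction = 0)
  expect_equal(nrow(xl0), 20)
  # with no noise, every link satisfies the cutoff on the ground truth
  all_xyz <- do.call(rbind, toy$truth)
  idx <- cumsum(c(0, head(vapply(toy$truth, nrow, integer(1)), -1)))
  names(idx) <- names(toy$truth)
  d <- vapply(seq_len(nrow(xl0)), function(i) {
    a <- all_xyz[idx[xl0$protein1[i]] + xl0$residue1[i], ]
    b <- all_xyz[idx[xl0$protein2[i]] + xl0$residue2[i], ]
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_true(all(d <= 21 + 1e-9))
  expect_true(all(!xl0$is_noise))
  expect_true(all(xl0$n_spectra >= 1))

  # noise_fraction 0.5, n_true 20 -> 40 links total
  set.seed(403)
  xl1 <- simulate_crosslinks(toy, n_true = 20, noise_fraction = 0.5)
  expect_equal(nrow(xl1), 40)
  expect_equal(sum(xl1$is_noise), 20)
  # determinism
  set.seed(403)
  xl2 <- simulate_crosslinks(toy, n_true = 20, noise_fraction = 0.5)
  expect_identical(as.data.frame(xl1), as.data.frame(xl2))
  expect_error(simulate_crosslinks(toy, n_true = 1e6), "eligible")
})

test_that("planted noise fraction is recovered over repeated draws", {
  toy <- small_toy()
  set.seed(404)
  viol <- replicate(30, {
    xl <- simulate_crosslinks(toy, n_true = 30, noise_fraction = 0.2)
    # violated fraction on the truth approximately the noise fraction
    all_xyz <- do.call(rbind, toy$truth)
    idx <- cumsum(c(0, head(vapply(toy$truth, nrow, integer(1)), -1)))
    names(idx) <- names(toy$truth)
    d <- vapply(seq_len(nrow(xl)), function(i) {
      a <- all_xyz[idx[xl$protein1[i]] + xl$residue1[i], ]
      b <- all_xyz[idx[xl$protein2[i]] + xl$residue2[i], ]
      sqrt(sum((a - b)^2))
    }, numeric(1))
    mean(d > 21)
  })
  n_noise <- ceiling(0.2 / 0.8 * 30)
  expected_max <- n_noise / (30 + n_noise)
  # noise links may satisfy the cutoff by chance (the toy is compact), so
  # the violated fraction sits at or below the planted fraction
  se <- sqrt(expected_max * (1 - expected_max) / (30 * (30 + n_noise)))
  expect_lt(mean(viol), expected_max + 3 * se)
  expect_gt(mean(viol), 0.03)
  # and only noise-labeled links are ever violated
  set.seed(408)
  xl <- simulate_crosslinks(toy, n_true = 30, noise_fraction = 0.2)
  all_xyz <- do.call(rbind, toy$truth)
  idx <- cumsum(c(0, head(vapply(toy$truth, nrow, integer(1)), -1)))
  names(idx) <- names(toy$truth)
  d <- vapply(seq_len(nrow(xl)), function(i) {
    a <- all_xyz[idx[xl$protein1[i]] + xl$residue1[i], ]
    b <- all_xyz[idx[xl$protein2[i]] + xl$residue2[i], ]
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_true(all(xl$is_noise[d > 21]))
})

test_that("simulated density is self-consistent and mass-weighted", {
  toy <- small_toy()
  dens <- simulate_density(toy)
  expect_equal(sum(dens$gmm$weights),
               sum(vapply(toy$models, function(m) sum(m$atoms$mass),
                          numeric(1))))
  # rasterized total density integrates to the total weight within 1%
  total <- sum(dens$map$data) * dens$map$spacing^3
  expect_equal(total, sum(dens$gmm$weights), tolerance = 0.01)
  # em_score of the emitted mixture against itself is 0
  expect_equal(em_score(dens$gmm, dens$gmm), 0, tolerance = 1e-9)
  # refit of the emitted map recovers the mixture (CC > 0.95)
  refit <- scale_gmm_mass(gmm_from_voxels(dens$map, length(dens$gmm$weights)),
                          sum(dens$gmm$weights))
  m2 <- rasterize_gmm(refit, origin = dens$map$origin,
                      spacing = dens$map$spacing, dims = dim(dens$map$data))
  expect_gt(map_cc(dens$map, m2), 0.95)
  # single-subunit, one component: Gaussian centered at the center of mass
  set.seed(405)
  toy1 <- make_toy_assembly(toy_assembly_spec(n_subunits = 1, lengths = 20))
  d1 <- simulate_density(toy1, blur = 0, res_per_comp = 100)
  expect_equal(as.numeric(d1$gmm$means[1, ]), colMeans(toy1$truth[[1]]),
               tolerance = 1e-6)
})

test_that("CSM tables have the declared target/decoy structure", {
  set.seed(406)
  tab <- simulate_csm_table(n_target = 100, decoy_ratio = 10)
  expect_equal(nrow(tab), 1100)
  expect_equal(sum(tab$is_decoy1 | tab$is_decoy2), 1000)
  set.seed(406)
  tab2 <- simulate_csm_table(n_target = 100, decoy_ratio = 10)
  expect_identical(tab, tab2)
  # with no score separation the corrected FDR near a low threshold is ~1
  set.seed(407)
  flat <- simulate_csm_table(n_target = 3000, decoy_ratio = 10,
                             score_separation = 0)
  expect_equal(estimate_fdr(flat, threshold = -1, decoy_ratio = 10), 1,
               tolerance = 0.05)
  # table passes through the filter machinery and the TSV round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  write_csm_table(tab, p)
  back <- read_csm_table(p)
  expect_equal(nrow(back), nrow(tab))
  filt <- filter_csms(back)
  expect_true(nrow(filt) > 0 && nrow(filt) < nrow(tab))
})
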