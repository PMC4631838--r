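csm_row <- function(spectrum_id = "s1", protein1 = "P1", protein2 = "P2",
                    peptide1 = "AKGLR", peptide2 = "VKDES",
                    residue1 = "10", residue2 = "20",
                    classifier_score = 2, peptide_score = 30,
                    expect_peptide = 1, expect_protein = 1, expect_worse = 1,
                    score_difference = 1, is_decoy1 = FALSE,
                    is_decoy2 = FALSE) {
  data.frame(spectrum_id = spectrum_id, protein1 = protein1,
             protein2 = protein2, peptide1 = peptide1, peptide2 = peptide2,
             residue1 = residue1, residue2 = residue2,
             classifier_score = classifier_score,
             peptide_score = peptide_score, expect_peptide = expect_peptide,
             expect_protein = expect_protein, expect_worse = expect_worse,
             score_difference = score_difference, is_decoy1 = is_decoy1,
             is_decoy2 = is_decoy2, stringsAsFactors = FALSE)
}

test_that("CSM filters apply score, expectation and length thresholds", {
  csms <- rbind(
    csm_row("s1", peptide_score = 19),              # below 20 -> removed
    csm_row("s2", peptide_score = 20),              # kept
    csm_row("s3", expect_protein = 51),             # above 50 -> removed
    csm_row("s4", score_difference = -0.1),         # below 0 -> removed
    csm_row("s5", peptide1 = "AKG"),                # 3-mer -> removed
    csm_row("s6", peptide1 = "AKGL"))               # 4-mer -> kept
  out <- filter_csms(csms)
  expect_setequal(out$spectrum_id, c("s2", "s6"))
  rm <- attr(out, "n_removed")
  expect_equal(unname(rm["scores"]), 3)
  expect_equal(unname(rm["short_peptide"]), 1)
  expect_error(filter_csms(csms[, -which(names(csms) == "peptide_score")]),
               "peptide_score")
})

test_that("competing interpretations follow the 0.3 decision-value rule", {
  # gap 0.2 < 0.3, both inter-protein -> ambiguous
  amb <- rbind(csm_row("s1", classifier_score = 2.0),
               csm_row("s1", protein2 = "P3", classifier_score = 1.8))
  out <- filter_csms(amb)
  expect_equal(nrow(out), 1)
  expect_true(all(out$ambiguous))

  # gap 0.4 > 0.3 -> unique top assignment
  clear <- rbind(csm_row("s2", classifier_score = 2.0),
                 csm_row("s2", protein2 = "P3", classifier_score = 1.6))
  out2 <- filter_csms(clear)
  expect_equal(nrow(out2), 1)
  expect_false(any(out2$ambiguous))
  expect_equal(out2$classifier_score, 2.0)

  # tie within gap resolved for the intra-protein interpretation
  tie <- rbind(csm_row("s3", protein2 = "P9", classifier_score = 2.0),
               csm_row("s3", protein1 = "P1", protein2 = "P1",
                       classifier_score = 1.9))
  out3 <- filter_csms(tie)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$protein2, "P1")
  expect_false(any(out3$ambiguous))
})

test_that("FDR follows the decoy-ratio formula", {
  mk <- function(n, score, decoy) {
    do.call(rbind, lapply(seq_len(n), function(i)
      csm_row(paste0("x", i, decoy, score[1]), classifier_score = score[i],
              is_decoy1 = decoy)))
  }
  csms <- rbind(mk(500, rep(1, 500), FALSE), mk(3, rep(-1, 3), TRUE))
  expect_equal(estimate_fdr(csms, threshold = 0, decoy_ratio = 10), 0)
  csms2 <- rbind(mk(1000, rep(1, 1000), FALSE), mk(40, rep(1, 40), TRUE))
  expect_equal(estimate_fdr(csms2, threshold = 0, decoy_ratio = 10), 0.004)
  expect_warning(fdr0 <- estimate_fdr(mk(5, rep(-2, 5), FALSE), threshold = 0),
                 "no target hits")
  expect_true(is.na(fdr0))
})

test_that("FDR on synthetic normal scores matches the analytic expectation", {
  set.seed(31)
  tab <- simulate_csm_table(n_target = 2000, decoy_ratio = 10,
                            score_separation = 3)
  thr <- 0
  got <- estimate_fdr(tab, threshold = thr, decoy_ratio = 10)
  # analytic oracle: decoys ~ N(0,1), targets ~ N(3,1), 10x decoys
  expected <- (10 * 2000 * pnorm(thr, 0, 1, lower.tail = FALSE) / 10) /
    (2000 * pnorm(thr, 3, 1, lower.tail = FALSE))
  # Monte-Carlo error of the ratio at these counts is ~ a few percent
  expect_equal(got, expected, tolerance = 0.1)
  # monotone non-increasing in the threshold on discriminating scores
  thrs <- c(-1, 0, 1, 2)
  fdrs <- vapply(thrs, function(t) estimate_fdr(tab, t, 10), numeric(1))
  expect_true(all(diff(fdrs) <= 1e-12))
})

test_that("dataset merge reproduces union arithmetic and is commutative", {
  a <- synthetic_link_set(260, offset = 0, source = "study")
  b <- synthetic_link_set(38, offset = 256, source = "published")
  m <- merge_crosslink_sets(a, b)
  expect_equal(nrow(m), 294)
  shared <- m[grepl(";", m$source), ]
  expect_equal(nrow(shared), 4)
  m2 <- merge_crosslink_sets(b, a)
  expect_equal(nrow(m2), 294)
  # commutative and associative under unordered-pair identity
  c3 <- synthetic_link_set(20, offset = 280, source = "c")
  key <- function(x) paste(x$protein1, x$residue1, x$protein2, x$residue2)
  expect_setequal(key(merge_crosslink_sets(merge_crosslink_sets(a, b), c3)),
                  key(merge_crosslink_sets(a, merge_crosslink_sets(b, c3))))
  # identity under empty merge
  e <- merge_crosslink_sets(a, crosslink_set())
  expect_equal(nrow(e), 260)
})

test_that("module classification partitions links by residue range", {
  topo <- topology_config(list(
    list(name = "Med17", length = 687,
         segments = list(list(range = c(1, 122), module = "Middle"),
                         list(range = c(123, 687), module = "Head"))),
    list(name = "Med21", length = 140,
         segments = list(list(range = c(1, 140), module = "Middle"))),
    list(name = "A", length = 50,
         segments = list(list(range = c(1, 50), module = "Head"))),
    list(name = "B", length = 50,
         segments = list(list(range = c(1, 50), module = "Tail")))))
  xs <- crosslink_set(data.frame(
    protein1 = c("Med17", "Med17", "A", "Med17"),
    residue1 = c(50L, 200L, 1L, 130L),
    protein2 = c("Med21", "Med21", "B", "Med17"),
    residue2 = c(30L, 30L, 1L, 300L),
    n_spectra = 1, source = "t", stringsAsFactors = FALSE))
  cl <- classify_crosslinks(xs, topo)
  lookup <- function(p1, r1) cl$xl_class[cl$protein1 == p1 & cl$residue1 == r1]
  expect_equal(lookup("Med17", 50), "intra_module")   # both Middle
  expect_equal(lookup("Med17", 200), "inter_module")  # Head vs Middle
  expect_equal(lookup("A", 1), "inter_module")
  expect_equal(lookup("Med17", 130), "intra_module")  # same subunit, same module
  expect_equal(sum(cl$xl_class == "intra_module") +
               sum(cl$xl_class == "inter_module"), nrow(cl))
  xs_bad <- crosslink_set(data.frame(protein1 = "Med21", residue1 = 141L,
    protein2 = "A", residue2 = 1L, n_spectra = 1, source = "t"))
  expect_error(classify_crosslinks(xs_bad, topo), "outside")
})

test_that("mapping links onto a structure flags violations beyond threshold", {
  n <- 12
  set.seed(9)
  xyz <- matrix(runif(3 * n, 0, 60), ncol = 3)
  m <- atomic_model(data.frame(chain = "A", resid = 1:n, elety = "CA",
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               mass = 12, stringsAsFactors = FALSE))
  pairs <- cbind(sample(n, 10, TRUE), sample(n, 10, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  xs <- crosslink_set(data.frame(protein1 = "A", residue1 = pairs[, 1],
                                 protein2 = "A", residue2 = pairs[, 2],
                                 n_spectra = 1, source = "t"))
  res <- map_crosslinks_to_structure(xs, m, threshold = 35)
  # brute-force oracle
  d_ref <- sqrt(rowSums((xyz[res$links$residue1, ] - xyz[res$links$residue2, ])^2))
  expect_equal(res$links$distance, d_ref, tolerance = 1e-12)
  expect_equal(res$links$violated, d_ref > 35)
  expect_equal(res$summary$n_mappable, nrow(res$links))

  # endpoints at identical coordinates; unmappable exclusion
  m2 <- atomic_model(data.frame(chain = "A", resid = 1:2, elety = "CA",
                                x = c(0, 36), y = 0, z = 0, mass = 12,
                                stringsAsFactors = FALSE))
  xs2 <- crosslink_set(data.frame(protein1 = c("A", "A"), residue1 = c(1L, 1L),
                                  protein2 = c("A", "B"), residue2 = c(2L, 5L),
                                  n_spectra = 1, source = "t"))
  res2 <- map_crosslinks_to_structure(xs2, m2, threshold = 35)
  expect_equal(res2$summary$n_mappable, 1)
  expect_equal(res2$summary$n_violated, 1)
})

test_that("site-ambiguous CSMs expand with divided spectral counts", {
  csms <- filter_csms(csm_row("s1", residue1 = "10;12", residue2 = "20"))
  xs <- csms_to_crosslinks(csms)
  expect_equal(nrow(xs), 2)
  expect_equal(xs$n_spectra, c(0.5, 0.5))
})

test_that("jackknife removes floor(fraction * n) links reproducibly", {
  xs <- synthetic_link_set(294)
  set.seed(77)
  jk <- jackknife_crosslinks(xs, 0.1)
  expect_equal(nrow(jk), 265)
  set.seed(77)
  jk2 <- jackknife_crosslinks(xs, 0.1)
  expect_identical(jk, jk2)
})
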