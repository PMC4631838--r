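test_that("forward model limit cases are exact and intermediate values match MC", {
  expect_identical(forward_model(50, 1, 1, 21), 0) # min distance 48 > 21
  expect_identical(forward_model(0, 1, 1, 21), 1)  # max distance 2 < 21
  set.seed(100)
  n <- 1e6
  rball <- function(n, r) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2)) * (runif(n)^(1 / 3) * r)
  }
  for (case in list(c(21, 5, 5, 21), c(25, 6, 4, 21), c(8, 10, 3, 9))) {
    d <- case[1]; a <- case[2]; b <- case[3]; L <- case[4]
    X <- rball(n, a); Y <- rball(n, b); Y[, 1] <- Y[, 1] + d
    mc <- mean(sqrt(rowSums((X - Y)^2)) <= L)
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(forward_model(d, a, b, L) - mc), 3 * se)
  }
})

test_that("forward model is monotone in distance and linker length", {
  set.seed(101)
  for (i in 1:20) {
    a <- runif(1, 0.5, 30); b <- runif(1, 0.5, 30); L <- runif(1, 5, 40)
    d <- sort(runif(6, 0, a + b + L + 10))
    f <- forward_model(d, a, b, L)
    expect_true(all(diff(f) <= 1e-12))
    Ls <- sort(runif(5, 1, 60))
    fl <- vapply(Ls, function(l) forward_model(d[3], a, b, l), numeric(1))
    expect_true(all(diff(fl) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("the R and compiled forward models agree", {
  set.seed(102)
  for (i in 1:50) {
    d <- runif(1, 0, 60); a <- runif(1, 0.5, 25); b <- runif(1, 0.5, 25)
    L <- runif(1, 2, 40)
    expect_equal(forward_model(d, a, b, L),
                 as.numeric(intarch:::ia_forward_model_cpp(d, a, b, L)),
                 tolerance = 1e-10)
  }
})

test_that("cross-link likelihood identities hold exactly", {
  expect_identical(crosslink_likelihood(1, 0.05), 0.95)
  expect_identical(crosslink_likelihood(0, 0.05), 0.05)
  for (psi in c(0.01, 0.3, 0.9))
    expect_equal(crosslink_likelihood(0.5, psi), 0.5)
})

test_that("cross-link score is an additive weighted negative log likelihood", {
  p <- restraint_params()
  psi <- c(intra_module = 0.05, inter_module = 0.2)
  # single satisfied link with f = 1 (d = 0), weight 1
  s1 <- crosslink_score(0, 1, "intra_module", sigma = 1, psi, p)
  expect_equal(s1, -log(0.95), tolerance = 1e-12)
  # additivity: two links = sum of singles
  d2 <- c(0, 30); ns <- c(1, 4); cls <- c("intra_module", "inter_module")
  s_joint <- crosslink_score(d2, ns, cls, sigma = 3, psi, p)
  s_sum <- crosslink_score(d2[1], ns[1], cls[1], 3, psi, p) +
    crosslink_score(d2[2], ns[2], cls[2], 3, psi, p)
  expect_equal(s_joint, s_sum, tolerance = 1e-9)
  # 10-link random state vs naive loop oracle
  set.seed(103)
  d <- runif(10, 0, 50); n <- sample(1:20, 10, TRUE)
  cl <- sample(names(psi), 10, TRUE)
  naive <- 0
  for (i in 1:10) {
    f <- forward_model(d[i], 3, 3, p$l_xl)
    pr <- psi[cl[i]] * (1 - f) + f * (1 - psi[cl[i]])
    naive <- naive - min(1 + log2(n[i]), 4) * log(pr)
  }
  expect_equal(crosslink_score(d, n, cl, 3, psi, p), unname(naive),
               tolerance = 1e-9)
  # moving a violated link closer lowers the score
  s_far <- crosslink_score(40, 1, "intra_module", 3, psi, p)
  s_near <- crosslink_score(25, 1, "intra_module", 3, psi, p)
  expect_lt(s_near, s_far)
})

test_that("redundancy weights grow logarithmically and cap", {
  expect_equal(redundancy_weight(1), 1)
  expect_equal(redundancy_weight(2), 2)
  expect_equal(redundancy_weight(4), 3)
  expect_equal(redundancy_weight(100), 4)
  expect_equal(redundancy_weight(20, cap = 6), 1 + log2(20))
})

test_that("GMM overlap matches the closed form and numerical integration", {
  I3 <- array(diag(3), dim = c(1, 3, 3))
  g1 <- gmm(1, matrix(0, 1, 3), I3, normalize = FALSE)
  expect_equal(gmm_overlap(g1, g1), (4 * pi)^(-3 / 2), tolerance = 1e-9)
  g_far <- gmm(1, matrix(c(1000, 0, 0), 1, 3), I3, normalize = FALSE)
  expect_lt(gmm_overlap(g1, g_far), 1e-20)
  # symmetry on random mixtures
  set.seed(104)
  for (i in 1:5) {
    a <- random_gmm(3); b <- random_gmm(2)
    expect_equal(gmm_overlap(a, b), gmm_overlap(b, a), tolerance = 1e-12)
  }
  # grid numerical integration oracle on a 2-vs-2 fixture
  a <- gmm(c(0.6, 0.4), rbind(c(0, 0, 0), c(6, 0, 0)),
           local({x <- array(0, dim = c(2, 3, 3))
                  x[1, , ] <- diag(3) * 4; x[2, , ] <- diag(3) * 9; x}))
  b <- gmm(c(0.5, 0.5), rbind(c(2, 1, 0), c(-3, 0, 2)),
           local({x <- array(0, dim = c(2, 3, 3))
                  x[1, , ] <- diag(3) * 5; x[2, , ] <- diag(3) * 7; x}))
  gr <- seq(-25, 30, by = 0.5)
  pts <- as.matrix(expand.grid(gr, gr, gr))
  num <- sum(gmm_density(a, pts) * gmm_density(b, pts)) * 0.5^3
  expect_equal(gmm_overlap(a, b), num, tolerance = 1e-3)
})

test_that("EM score is zero iff mixtures coincide and matches integration", {
  set.seed(105)
  for (i in 1:5) {
    g <- random_gmm(sample(1:4, 1))
    expect_equal(em_score(g, g), 0, tolerance = 1e-9)
  }
  g1 <- random_gmm(2)
  g2 <- transform_gmm(g1, t = c(500, 0, 0))
  s <- em_score(g1, g2)
  expect_true(is.finite(s) && s > 1000)
  # numeric-integration oracle for the CC on a 2-vs-2 fixture
  a <- gmm(c(0.6, 0.4), rbind(c(0, 0, 0), c(6, 0, 0)),
           local({x <- array(0, dim = c(2, 3, 3))
                  x[1, , ] <- diag(3) * 4; x[2, , ] <- diag(3) * 9; x}))
  b <- gmm(c(0.5, 0.5), rbind(c(2, 1, 0), c(-3, 0, 2)),
           local({x <- array(0, dim = c(2, 3, 3))
                  x[1, , ] <- diag(3) * 5; x[2, , ] <- diag(3) * 7; x}))
  gr <- seq(-25, 30, by = 0.5)
  pts <- as.matrix(expand.grid(gr, gr, gr))
  fa <- gmm_density(a, pts); fb <- gmm_density(b, pts)
  cc_num <- 2 * sum(fa * fb) / sum(fa^2 + fb^2)
  expect_equal(em_score(a, b, scale = 100), -100 * log(cc_num),
               tolerance = 1e-3)
})

test_that("excluded volume and connectivity follow their threshold rules", {
  b <- data.frame(subunit = "S", res_first = c(1L, 11L), res_last = c(10L, 20L),
                  n_res = 10L, x = c(0, 10), y = 0, z = 0, radius = 3,
                  mass = 1, scale = "coarse", rigid_id = NA_integer_,
                  mobile = TRUE)
  expect_equal(excluded_volume_score(b), 0)           # distance 10 > 6
  b2 <- b; b2$x <- c(0, 4)                            # overlap 2
  expect_equal(excluded_volume_score(b2), 0.5 * 2^2)
  b2$rigid_id <- c(1L, 1L)                            # same rigid body exempt
  expect_equal(excluded_volume_score(b2), 0)

  pairs <- cbind(1L, 2L)
  b3 <- b; b3$x <- c(0, 24)                           # exactly 4 * (3 + 3)
  expect_equal(connectivity_score(b3, pairs), 0)
  b3$x <- c(0, 25)
  expect_equal(connectivity_score(b3, pairs), 0.5 * 1^2)
  # default pair detection: consecutive non-fine beads, same subunit
  expect_equal(nrow(connectivity_pairs(b3)), 1)
})

test_that("linear and sigma priors are simple closed forms", {
  expect_equal(linear_prior(10, 0.01), 0.1)
  expect_equal(linear_prior(c(10, 20)), 0.3)
  expect_identical(sigma_prior(50), 0)
  expect_identical(sigma_prior(-1), Inf)
  expect_identical(sigma_prior(101), Inf)
})

test_that("total score equals the sum of its terms and the C++ sweep agrees", {
  sys <- small_system()
  st <- model_state(sys)
  sc <- total_score(st, sys)
  expect_equal(sc$total,
               sc$crosslink + sc$em + sc$excluded_volume + sc$connectivity +
               sc$linear + sc$tether + sc$sigma_prior, tolerance = 1e-9)
  # C++ incremental scoring reproduces the R evaluation on sampled frames
  tr <- run_metropolis(sys, n_sweeps = 50, seed = 5, save_interval = 10)
  for (i in c(1, 5)) {
    stf <- frame_state(tr, i, sys)
    scR <- total_score(stf, sys)
    expect_equal(scR$total, tr$scores$total[i], tolerance = 1e-6)
    expect_equal(scR$crosslink, tr$scores$crosslink[i], tolerance = 1e-6)
    expect_equal(scR$em, tr$scores$em[i], tolerance = 1e-6)
  }
})
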