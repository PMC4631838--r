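# shared fixtures built in code

# tiny deterministic 3-residue synthetic PDB
write_tiny_pdb <- function(path, resids = 1:3,
                           xyz = cbind((resids - 1) * 3.8, 0, 0)) {
  m <- atomic_model(data.frame(chain = "A", resid = resids, elety = "CA",
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               mass = 12.011, stringsAsFactors = FALSE))
  write_structure(m, path)
  path
}

random_gmm <- function(k, spread = 20) {
  means <- matrix(runif(3 * k, -spread, spread), ncol = 3)
  covs <- array(0, dim = c(k, 3, 3))
  for (i in seq_len(k)) {
    a <- matrix(rnorm(9), 3, 3)
    covs[i, , ] <- crossprod(a) + diag(3)
  }
  gmm(runif(k, 0.5, 2), means, covs)
}

# small toy assembly reused across tests (built once per test run)
small_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4242)
      cache <<- make_toy_assembly(toy_assembly_spec(
        n_subunits = 3, lengths = c(20, 25, 30),
        contacts = rbind(c(1, 2), c(2, 3))))
    }
    cache
  }
})

small_system <- function(seed = 4242) {
  set.seed(seed)
  toy <- small_toy()
  dens <- simulate_density(toy, blur = 3)
  xl <- simulate_crosslinks(toy, n_true = 20)
  assembly_system(toy$beads, toy$gaussians, dens$by_module, xl)
}
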