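#' Specification of a synthetic toy assembly
#'
#' The generator emulates the inputs of an integrative modeling study:
#' a multi-subunit assembly of compact rigid subunits realizing a declared
#' contact graph, with module labels driving the per-module density
#' restraint and the cross-link classes. Subunits are random self-avoiding
#' Calpha chains folded into compact globules — scoring and sampling
#' depend only on bead geometry, not on real folds.
#'
#' @param n_subunits subunit count.
#' @param lengths per-subunit residue counts (recycled). The default
#'   staggers sizes (30, 40, 50, ... residues): heterogeneous subunits
#'   give the density map distinguishable lobes, as in real assemblies.
#' @param modules per-subunit module labels (default: first half `"M1"`,
#'   second half `"M2"`, driving the density segmentation and the
#'   link classes).
#' @param contacts 2-column matrix of subunit index pairs required to be
#'   in contact (default: a closed ring for >= 3 subunits, a chain
#'   otherwise — compact assemblies leave no singly-anchored subunits).
#'   Must be connected.
#' @param fixed_subunits indices of subunits kept fixed during sampling
#'   (default 1, anchoring the global frame like a docked component).
#' @return list of class `toy_assembly_spec`.
#' @export
toy_assembly_spec <- function(n_subunits = 4, lengths = NULL, modules = NULL,
                              contacts = NULL, fixed_subunits = 1) {
  if (is.null(lengths)) lengths <- seq(30, by = 10, length.out = n_subunits)
  lengths <- rep_len(lengths, n_subunits)
  if (any(lengths < 1)) stop("subunit lengths must be >= 1")
  if (is.null(modules))
    modules <- ifelse(seq_len(n_subunits) <= ceiling(n_subunits / 2), "M1", "M2")
  if (is.null(contacts) && n_subunits > 1) {
    contacts <- cbind(seq_len(n_subunits - 1), 2:n_subunits)
    if (n_subunits >= 3) contacts <- rbind(contacts, c(n_subunits, 1L))
  }
  if (!is.null(contacts)) {
    g <- seq_len(n_subunits)
    for (rep_i in seq_len(n_subunits)) # union-find by repeated relabeling
      for (e in seq_len(nrow(contacts))) {
        a <- g[contacts[e, 1]]; b <- g[contacts[e, 2]]
        g[g == max(a, b)] <- min(a, b)
      }
    if (length(unique(g)) != 1L) stop("contact graph must be connected")
  }
  structure(list(n_subunits = n_subunits, lengths = lengths,
                 modules = modules, contacts = contacts,
                 fixed_subunits = fixed_subunits),
            class = "toy_assembly_spec")
}

# compact self-avoiding chain: bond length 3.8 A, non-neighbors >= 3.8 A,
# confined to a sphere sized for the chain's molecular volume
.toy_chain <- function(n, max_tries = 2000) {
  conf <- bead_radius(n) * 1.4
  for (try in seq_len(max_tries)) {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    for (i in seq_len(n - 1)[n > 1]) {
      placed <- FALSE
      for (att in 1:50) {
        u <- stats::rnorm(3)
        cand <- xyz[i, ] + 3.8 * u / sqrt(sum(u^2))
        if (sqrt(sum((cand - colMeans(xyz[seq_len(i), , drop = FALSE]))^2)) > conf) next
        if (i > 1) {
          d2 <- rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
          if (min(d2) < 3.8^2) next
        }
        xyz[i + 1, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(sweep(xyz, 2, colMeans(xyz)))
  }
  stop("failed to generate a self-avoiding chain after ", max_tries, " tries")
}

#' Generate a toy assembly with known ground truth
#'
#' Places the subunits as non-overlapping compact chains realizing the
#' contact graph (surface distance of contacting subunits below 10 A,
#' non-contacting subunits non-overlapping), and builds the full
#' multi-scale representation: fine beads at every Calpha, 10-residue
#' coarse beads, and one Gaussian per 50 residues (minimum 1) per subunit.
#' Deterministic given the RNG state.
#'
#' @param spec a [toy_assembly_spec()].
#' @param max_tries placement retry limit.
#' @return list of class `toy_assembly`: `truth` (per-subunit fine
#'   coordinate matrices), `beads` (fine + coarse, with `rigid_id` =
#'   subunit index and `mobile` flags), `gaussians` (model Gaussians with
#'   attachments), `models` (per-subunit [atomic_model()]s), `topology`
#'   (a [topology_config()]), `spec`.
#' @export
make_toy_assembly <- function(spec = toy_assembly_spec(), max_tries = 50) {
  ns <- spec$n_subunits
  names_su <- LETTERS[seq_len(ns)]
  chains <- lapply(spec$lengths, .toy_chain)
  radii <- vapply(chains, function(x) max(sqrt(rowSums(x^2))) + 2, numeric(1))
  centers <- matrix(0, ns, 3)
  # placement by global relaxation: contacting subunits are pulled until
  # their closest Calpha pair sits at a small target gap, non-contacting
  # subunits are pushed apart; subunit 1 stays at the origin
  if (ns > 1) {
    is_contact <- matrix(FALSE, ns, ns)
    for (e in seq_len(nrow(spec$contacts)))
      is_contact[spec$contacts[e, 1], spec$contacts[e, 2]] <-
        is_contact[spec$contacts[e, 2], spec$contacts[e, 1]] <- TRUE
    pair_gap <- function(a, b) {
      A <- sweep(chains[[a]], 2, centers[a, ], `+`)
      B <- sweep(chains[[b]], 2, centers[b, ], `+`)
      cross <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      sqrt(max(min(cross), 0))
    }
    done <- FALSE
    for (try in seq_len(max_tries)) {
      for (s in 2:ns) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        centers[s, ] <- u * stats::runif(1, 0.8, 1.6) * (radii[1] + radii[s])
      }
      target <- 6
      for (it in 1:250) {
        moved <- 0
        for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
          g <- pair_gap(a, b)
          axis <- centers[b, ] - centers[a, ]
          nn <- sqrt(sum(axis^2)); if (nn < 1e-9) { axis <- c(1, 0, 0); nn <- 1 }
          axis <- axis / nn
          err <- if (is_contact[a, b]) g - target else min(g - 13, 0)
          if (abs(err) > 0.5) {
            step <- 0.5 * err
            if (a == 1L) centers[b, ] <- centers[b, ] - axis * step
            else { centers[a, ] <- centers[a, ] + axis * step / 2
                   centers[b, ] <- centers[b, ] - axis * step / 2 }
            moved <- moved + abs(step)
          }
        }
        if (moved < 0.1) break
      }
      ok <- TRUE
      for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
        g <- pair_gap(a, b)
        if (is_contact[a, b] && (g < 3.5 || g > 10)) ok <- FALSE
        if (!is_contact[a, b] && g < 12) ok <- FALSE
      }
      if (ok) { done <- TRUE; break }
    }
    if (!done) stop("infeasible packing after ", max_tries, " tries")
  }
  truth <- lapply(seq_len(ns), function(s) sweep(chains[[s]], 2, centers[s, ], `+`))
  names(truth) <- names_su
  models <- lapply(seq_len(ns), function(s) {
    xyz <- truth[[s]]
    atomic_model(data.frame(chain = names_su[s], resid = seq_len(nrow(xyz)),
                            elety = "CA", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], mass = 110,
                            stringsAsFactors = FALSE))
  })
  names(models) <- names_su
  beads <- do.call(rbind, lapply(seq_len(ns), function(s) {
    fine <- build_beads(models[[s]], "fine", subunit = names_su[s])
    coarse <- build_beads(models[[s]], "coarse", subunit = names_su[s])
    b <- rbind(fine, coarse)
    b$rigid_id <- s
    b$mobile <- !(s %in% spec$fixed_subunits)
    b
  }))
  rownames(beads) <- NULL
  gsub_list <- lapply(seq_len(ns), function(s)
    gmm_from_structure(models[[s]]))
  g_all <- list(
    gmm = gmm(weights = unlist(lapply(gsub_list, function(g) g$weights)),
              means = do.call(rbind, lapply(gsub_list, function(g) g$means)),
              covs = local({
                ks <- vapply(gsub_list, function(g) length(g$weights), integer(1))
                a <- array(0, dim = c(sum(ks), 3, 3))
                off <- 0
                for (s in seq_len(ns)) {
                  for (i in seq_len(ks[s])) a[off + i, , ] <- gsub_list[[s]]$covs[i, , ]
                  off <- off + ks[s]
                }
                a
              }), normalize = FALSE),
    rigid_id = rep(seq_len(ns),
                   vapply(gsub_list, function(g) length(g$weights), integer(1))),
    bead = rep(NA_integer_, sum(vapply(gsub_list, function(g) length(g$weights), integer(1)))),
    module = rep(spec$modules,
                 vapply(gsub_list, function(g) length(g$weights), integer(1))))
  topo <- topology_config(lapply(seq_len(ns), function(s) {
    list(name = names_su[s], length = spec$lengths[s],
         segments = list(list(range = c(1L, spec$lengths[s]),
                              module = spec$modules[s], rigid_body = s,
                              chain = names_su[s],
                              fixed = s %in% spec$fixed_subunits)))
  }))
  structure(list(truth = truth, beads = beads, gaussians = g_all,
                 models = models, topology = topo, spec = spec),
            class = "toy_assembly")
}

#' Simulate a cross-link dataset from ground truth
#'
#' Samples `n_true` distinct residue pairs whose true Calpha distance is
#' at most `cutoff` (excluding trivially close sequence neighbors within
#' the same subunit), plus `ceiling(noise_fraction / (1 - noise_fraction)
#' * n_true)` distinct uniformly random pairs. Spectral counts follow
#' `1 + Geometric(spectra_p)`. The hidden `is_noise` column labels the
#' planted status of each link for recovery tests; noise links may
#' occasionally satisfy the cutoff by chance.
#'
#' @param toy a `toy_assembly`.
#' @param n_true number of distance-consistent links.
#' @param cutoff generation cutoff in Angstrom (default 21, the linker
#'   length).
#' @param noise_fraction fraction of the final dataset that is noise.
#' @param spectra_p geometric law parameter for spectral counts.
#' @param min_seq_sep minimum intra-subunit sequence separation.
#' @param include_intra sample consistent links from intra-subunit pairs
#'   as well (default FALSE: a link within a rigid subunit has a fixed
#'   length and carries no information about the assembly, and the
#'   between-subunit link counts are what drive assembly modeling; noise
#'   links are always drawn over all pairs).
#' @return a [crosslink_set()] with `xl_class` (from the toy topology) and
#'   `is_noise` columns.
#' @export
simulate_crosslinks <- function(toy, n_true = 50, cutoff = 21,
                                noise_fraction = 0.05, spectra_p = 0.5,
                                min_seq_sep = 5, include_intra = FALSE) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1, cutoff > 0)
  su <- names(toy$truth)
  all_xyz <- do.call(rbind, toy$truth)
  idx <- do.call(rbind, lapply(seq_along(su), function(s)
    data.frame(protein = su[s], residue = seq_len(nrow(toy$truth[[s]])),
               stringsAsFactors = FALSE)))
  n <- nrow(all_xyz)
  dmat <- as.matrix(stats::dist(all_xyz))
  same_su <- outer(idx$protein, idx$protein, `==`)
  seq_sep <- abs(outer(idx$residue, idx$residue, `-`))
  eligible <- dmat <= cutoff & upper.tri(dmat) &
    (!same_su | (include_intra & seq_sep >= min_seq_sep))
  elig_idx <- which(eligible, arr.ind = TRUE)
  if (nrow(elig_idx) < n_true)
    stop("fewer than n_true eligible pairs (", nrow(elig_idx), ")")
  pick <- elig_idx[sample.int(nrow(elig_idx), n_true), , drop = FALSE]
  n_noise <- ceiling(noise_fraction / (1 - noise_fraction) * n_true)
  taken <- paste(pick[, 1], pick[, 2])
  noise <- matrix(0L, 0, 2)
  while (nrow(noise) < n_noise) {
    i <- sample.int(n, 1); j <- sample.int(n, 1)
    if (i == j) next
    a <- min(i, j); b <- max(i, j)
    if (same_su[a, b] && seq_sep[a, b] < min_seq_sep) next
    key <- paste(a, b)
    if (key %in% taken) next
    taken <- c(taken, key)
    noise <- rbind(noise, c(a, b))
  }
  pairs <- rbind(cbind(pick[, 1], pick[, 2]), noise)
  is_noise <- rep(c(FALSE, TRUE), c(n_true, nrow(noise)))
  df <- data.frame(protein1 = idx$protein[pairs[, 1]],
                   residue1 = idx$residue[pairs[, 1]],
                   protein2 = idx$protein[pairs[, 2]],
                   residue2 = idx$residue[pairs[, 2]],
                   n_spectra = 1 + stats::rgeom(nrow(pairs), spectra_p),
                   source = "synthetic",
                   is_noise = is_noise, stringsAsFactors = FALSE)
  classify_crosslinks(crosslink_set(df), toy$topology)
}

#' Simulate an electron density from ground truth
#'
#' Fits per-subunit Gaussians to the true Calpha positions (one component
#' per `res_per_comp` residues, minimum one), inflates every covariance by
#' `blur^2` on the diagonal to emulate limited resolution, groups
#' components per module with weights proportional to subunit mass, and
#' rasterizes the combined mixture. The defaults (25 residues per data
#' component, 3 A blur) emulate an intermediate-resolution map whose
#' features are ~15 A across; the model representation keeps its own
#' 50-residue component rule.
#'
#' @param toy a `toy_assembly`.
#' @param blur isotropic blurring in Angstrom.
#' @param res_per_comp residues per data-density component.
#' @param spacing rasterization voxel size.
#' @return list with `gmm` (whole assembly), `by_module` (named list of
#'   per-module [gmm()]s, mass weights), `map` (a [voxel_map()]).
#' @export
simulate_density <- function(toy, blur = 3, res_per_comp = 25, spacing = 4) {
  su <- names(toy$truth)
  comps <- lapply(seq_along(su), function(s) {
    k <- max(1L, nrow(toy$truth[[s]]) %/% res_per_comp)
    g <- gmm_from_structure(toy$models[[s]], n_components = k)
    for (i in seq_along(g$weights))
      g$covs[i, , ] <- g$covs[i, , ] + diag(rep(blur^2, 3))
    g
  })
  modules <- toy$spec$modules
  cat_gmms <- function(gs) {
    ks <- vapply(gs, function(g) length(g$weights), integer(1))
    a <- array(0, dim = c(sum(ks), 3, 3))
    off <- 0
    for (s in seq_along(gs)) {
      for (i in seq_len(ks[s])) a[off + i, , ] <- gs[[s]]$covs[i, , ]
      off <- off + ks[s]
    }
    gmm(weights = unlist(lapply(gs, function(g) g$weights)),
        means = do.call(rbind, lapply(gs, function(g) g$means)),
        covs = a, normalize = FALSE)
  }
  by_module <- lapply(unique(modules), function(m)
    cat_gmms(comps[modules == m]))
  names(by_module) <- unique(modules)
  whole <- cat_gmms(by_module)
  list(gmm = whole, by_module = by_module,
       map = rasterize_gmm(whole, spacing = spacing))
}

#' Simulate a cross-link spectral match table
#'
#' Target classifier scores are N(`score_separation`, 1), decoy scores
#' N(0, 1), with `decoy_ratio` times as many decoy as target rows
#' (emulating a search against a 10x randomized decoy database). The
#' auxiliary search-engine scores and peptide lengths span the filter
#' thresholds so the table exercises [filter_csms()].
#'
#' @param n_target target CSM count.
#' @param decoy_ratio decoy/target count ratio.
#' @param score_separation mean decision-value separation.
#' @return a CSM data.frame (see [read_csm_table()]).
#' @export
simulate_csm_table <- function(n_target = 100, decoy_ratio = 10,
                               score_separation = 3) {
  stopifnot(decoy_ratio >= 1)
  n_decoy <- as.integer(decoy_ratio * n_target)
  n <- n_target + n_decoy
  is_decoy <- rep(c(FALSE, TRUE), c(n_target, n_decoy))
  pep <- function(k) vapply(k, function(len)
    paste(sample(c("A", "G", "L", "K", "S", "V", "E", "D"), len, TRUE),
          collapse = ""), character(1))
  len1 <- sample(3:12, n, TRUE); len2 <- sample(3:12, n, TRUE)
  prot <- paste0("P", sample.int(8, n, TRUE))
  prot2 <- paste0("P", sample.int(8, n, TRUE))
  df <- data.frame(
    spectrum_id = sprintf("sp%06d", seq_len(n)),
    protein1 = ifelse(is_decoy, paste0("decoy_", prot), prot),
    peptide1 = pep(len1),
    residue1 = as.character(sample.int(200, n, TRUE)),
    protein2 = ifelse(is_decoy & stats::runif(n) < 0.5,
                      paste0("decoy_", prot2), prot2),
    peptide2 = pep(len2),
    residue2 = as.character(sample.int(200, n, TRUE)),
    classifier_score = stats::rnorm(n, ifelse(is_decoy, 0, score_separation), 1),
    peptide_score = stats::rnorm(n, 30, 8),
    expect_peptide = stats::rexp(n, 1 / 20),
    expect_protein = stats::rexp(n, 1 / 20),
    expect_worse = stats::rexp(n, 1 / 20),
    score_difference = stats::rnorm(n, 1, 1),
    is_decoy1 = is_decoy,
    is_decoy2 = is_decoy & grepl("^decoy_", ifelse(is_decoy, paste0("decoy_", prot2), prot2)),
    stringsAsFactors = FALSE)
  df$is_decoy2 <- grepl("^decoy_", df$protein2)
  df
}

#' Build a synthetic cross-link set of a given size
#'
#' Utility for dataset-merge arithmetic: a set of `n` distinct links
#' labeled `source`, with pairs drawn from a deterministic enumeration so
#' that two sets built with overlapping index ranges share exactly the
#' intended pairs.
#'
#' @param n number of links.
#' @param offset starting index of the enumeration (controls overlap
#'   between sets).
#' @param source dataset label.
#' @return a [crosslink_set()].
#' @export
synthetic_link_set <- function(n, offset = 0, source = "setA") {
  i <- offset + seq_len(n)
  crosslink_set(data.frame(
    protein1 = paste0("S", 1 + (i - 1) %/% 50),
    residue1 = 1 + (i - 1) %% 50,
    protein2 = paste0("S", 10 + (i - 1) %/% 50),
    residue2 = 1 + (i * 7) %% 97,
    n_spectra = 1, source = source, stringsAsFactors = FALSE))
}
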