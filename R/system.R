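#' Assemble a scoring system
#'
#' Binds together everything the scoring function needs: the multi-scale
#' bead table, the model Gaussians (with their rigid-body or flexible-bead
#' attachments and module labels), the per-module data density mixtures,
#' the cross-link table mapped to scoring beads, optional harmonic tethers,
#' and the restraint parameters. Cross-link endpoints are scored on the
#' fine beads of structured regions and on the coarse beads of flexible
#' strings.
#'
#' @param beads bead data.frame (see [build_beads()]); row order defines
#'   bead indices. Columns `rigid_id` (NA = not in a rigid body) and
#'   `mobile` control sampling.
#' @param gaussians list with elements `gmm` (a [gmm()], mass weights),
#'   `rigid_id` (per-component rigid body or NA), `bead` (per-component
#'   flexible bead row index or NA), `module` (per-component module label).
#'   NULL disables the EM restraint.
#' @param data_gmm named list of per-module data [gmm()]s (mass weights);
#'   NULL disables the EM restraint.
#' @param crosslinks a [crosslink_set()] with an `xl_class` column, or NULL.
#' @param params a [restraint_params()] list.
#' @param tethers optional data.frame (`bead`, `x`, `y`, `z`, `k`) of
#'   harmonic position restraints `0.5 k d^2` on single beads.
#' @return object of class `assembly_system`.
#' @export
assembly_system <- function(beads, gaussians = NULL, data_gmm = NULL,
                            crosslinks = NULL, params = restraint_params(),
                            tethers = NULL) {
  rownames(beads) <- NULL
  xl <- NULL
  if (!is.null(crosslinks) && nrow(crosslinks) > 0L) {
    if (is.null(crosslinks$xl_class))
      stop("crosslinks must carry an 'xl_class' column (see classify_crosslinks)")
    b1 <- .endpoint_bead(beads, crosslinks$protein1, crosslinks$residue1)
    b2 <- .endpoint_bead(beads, crosslinks$protein2, crosslinks$residue2)
    xl <- data.frame(bead1 = b1, bead2 = b2,
                     n_spectra = crosslinks$n_spectra,
                     xl_class = crosslinks$xl_class,
                     protein1 = crosslinks$protein1,
                     residue1 = crosslinks$residue1,
                     protein2 = crosslinks$protein2,
                     residue2 = crosslinks$residue2,
                     stringsAsFactors = FALSE)
  }
  if (!is.null(gaussians) && is.null(data_gmm))
    stop("model gaussians given without per-module data_gmm")
  structure(list(beads = beads, gaussians = gaussians, data_gmm = data_gmm,
                 crosslinks = xl, params = params, tethers = tethers,
                 conn_pairs = connectivity_pairs(beads)),
            class = "assembly_system")
}

# scoring bead for an endpoint: fine bead if the residue has one, else the
# coarse/flexible bead covering it
.endpoint_bead <- function(beads, protein, residue) {
  out <- integer(length(protein))
  for (i in seq_along(protein)) {
    in_range <- beads$subunit == protein[i] &
      beads$res_first <= residue[i] & beads$res_last >= residue[i]
    fine <- which(in_range & beads$scale == "fine")
    if (length(fine)) { out[i] <- fine[1]; next }
    other <- which(in_range)
    if (!length(other))
      stop("cross-link endpoint maps to no bead: ", protein[i], ":", residue[i])
    out[i] <- other[1]
  }
  out
}

#' Initial model state for a system
#'
#' @param system an [assembly_system()].
#' @param sigma,psi initial nuisance values; `psi` must be a named vector
#'   covering every cross-link class in the system.
#' @return object of class `model_state` with elements `coords` (n x 3),
#'   `gmeans`/`gcovs` (model Gaussian parameters), `sigma`, `psi`.
#' @export
model_state <- function(system, sigma = 5,
                        psi = c(intra_module = 0.05, inter_module = 0.05)) {
  coords <- as.matrix(system$beads[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  g <- system$gaussians
  structure(list(coords = coords,
                 gmeans = if (is.null(g)) NULL else g$gmm$means,
                 gcovs = if (is.null(g)) NULL else g$gmm$covs,
                 sigma = sigma, psi = psi),
            class = "model_state")
}

#' Mobile elements of a system
#' @param system an [assembly_system()].
#' @return list with `rigid` (mobile rigid-body ids) and `flexible`
#'   (mobile bead row indices outside rigid bodies).
#' @export
mobile_elements <- function(system) {
  b <- system$beads
  rb <- unique(b$rigid_id[!is.na(b$rigid_id) & b$mobile])
  flex <- which(is.na(b$rigid_id) & b$mobile)
  list(rigid = sort(rb), flexible = flex)
}

#' Full Bayesian score of a model state
#'
#' Negative log posterior: cross-link likelihood, per-module EM restraint,
#' excluded volume (coarse scale, intra-rigid pairs exempt), sequence
#' connectivity, the weak linear distance prior, tethers, and the sigma
#' prior. Per-term breakdown retained; the total equals the sum of terms.
#'
#' @param state a [model_state()].
#' @param system an [assembly_system()].
#' @return list of per-term scores plus `total`.
#' @export
total_score <- function(state, system) {
  p <- system$params
  b <- system$beads
  b$x <- state$coords[, 1]; b$y <- state$coords[, 2]; b$z <- state$coords[, 3]
  terms <- list(crosslink = 0, em = 0, excluded_volume = 0,
                connectivity = 0, linear = 0, tether = 0, sigma_prior = 0)
  if (!is.null(system$crosslinks)) {
    xl <- system$crosslinks
    d <- sqrt(rowSums((state$coords[xl$bead1, , drop = FALSE] -
                       state$coords[xl$bead2, , drop = FALSE])^2))
    terms$crosslink <- crosslink_score(d, xl$n_spectra, xl$xl_class,
                                       state$sigma, state$psi, p)
    terms$linear <- linear_prior(d, p$slope)
  }
  if (!is.null(system$gaussians)) {
    g <- system$gaussians
    for (m in names(system$data_gmm)) {
      sel <- which(g$module == m)
      if (!length(sel)) next
      mg <- gmm(g$gmm$weights[sel], state$gmeans[sel, , drop = FALSE],
                state$gcovs[sel, , , drop = FALSE], normalize = FALSE)
      terms$em <- terms$em + em_score(mg, system$data_gmm[[m]], p$em_scale)
    }
  }
  coarse <- b[b$scale != "fine", , drop = FALSE]
  terms$excluded_volume <- excluded_volume_score(coarse, p$k_excluded)
  terms$connectivity <- connectivity_score(b, system$conn_pairs,
                                           p$connectivity_factor, p$k_connect)
  if (!is.null(system$tethers)) {
    th <- system$tethers
    d2 <- (state$coords[th$bead, 1] - th$x)^2 +
      (state$coords[th$bead, 2] - th$y)^2 +
      (state$coords[th$bead, 3] - th$z)^2
    terms$tether <- sum(0.5 * th$k * d2)
  }
  terms$sigma_prior <- sigma_prior(state$sigma, p$sigma_min, p$sigma_max)
  terms$total <- sum(unlist(terms))
  terms
}
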