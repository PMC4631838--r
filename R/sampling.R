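#' Monte Carlo move parameters
#'
#' Maximum sizes of the elementary proposals: rigid-body translations up to
#' 2 A and rotations up to 0.04 rad about a uniformly random axis; flexible
#' bead translations up to 3 A; uniform steps of +-0.5 A on sigma and
#' +-0.02 on each psi. Proposals are symmetric; nuisance proposals falling
#' outside the prior support are rejected. The per-class uncertainty psi is
#' bounded in (0.01, 0.49): at psi = 0.5 the likelihood becomes flat in the
#' forward model and reported links would stop informing the structure, so
#' the prior support stays below it.
#'
#' @param ... overrides.
#' @return named list.
#' @export
move_params <- function(...) {
  utils::modifyList(list(rigid_trans = 2, rigid_rot = 0.04, flex_trans = 3,
                         sigma_step = 0.5, psi_step = 0.02,
                         psi_min = 0.01, psi_max = 0.49,
                         sigma_move_min = 0.5), list(...))
}

# uniform point in a ball of radius r (rejection from the cube)
.runif_ball <- function(r) {
  repeat {
    v <- stats::runif(3, -1, 1)
    if (sum(v^2) <= 1) return(v * r)
  }
}

# rotation matrix: random axis (isotropic), angle uniform in [-amax, amax]
.random_rotation <- function(amax) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -amax, amax)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Propose a Monte Carlo move
#'
#' Perturbs one element of the state: a mobile rigid body (rotation about
#' its bead centroid plus translation, applied to member beads and
#' Gaussians), a mobile flexible bead (translation, carrying its attached
#' Gaussian), or a nuisance parameter. All proposals are symmetric.
#'
#' @param state a [model_state()].
#' @param system an [assembly_system()].
#' @param element list(`type` = "rigid"/"flexible"/"sigma"/"psi", `id`);
#'   default: one of the mobile coordinate elements chosen uniformly.
#' @param mp a [move_params()] list.
#' @return the proposed state (attribute `element` records what moved;
#'   attribute `rejected` is TRUE for out-of-bounds nuisance proposals).
#' @export
propose_move <- function(state, system, element = NULL, mp = move_params()) {
  if (is.null(element)) {
    mob <- mobile_elements(system)
    n <- length(mob$rigid) + length(mob$flexible)
    if (n == 0L) stop("no mobile elements in the system")
    k <- sample.int(n, 1)
    element <- if (k <= length(mob$rigid))
      list(type = "rigid", id = mob$rigid[k])
    else list(type = "flexible", id = mob$flexible[k - length(mob$rigid)])
  }
  st <- state
  g <- system$gaussians
  if (element$type == "rigid") {
    mem <- which(!is.na(system$beads$rigid_id) &
                 system$beads$rigid_id == element$id)
    ctr <- colMeans(state$coords[mem, , drop = FALSE])
    R <- .random_rotation(mp$rigid_rot)
    tr <- .runif_ball(mp$rigid_trans)
    st$coords[mem, ] <- t(R %*% (t(state$coords[mem, , drop = FALSE]) - ctr) +
                            ctr + tr)
    if (!is.null(g)) {
      gsel <- which(!is.na(g$rigid_id) & g$rigid_id == element$id)
      for (i in gsel) {
        st$gmeans[i, ] <- as.numeric(R %*% (state$gmeans[i, ] - ctr) + ctr + tr)
        st$gcovs[i, , ] <- R %*% state$gcovs[i, , ] %*% t(R)
      }
    }
  } else if (element$type == "flexible") {
    tr <- .runif_ball(mp$flex_trans)
    st$coords[element$id, ] <- state$coords[element$id, ] + tr
    if (!is.null(g)) {
      gsel <- which(!is.na(g$bead) & g$bead == element$id)
      for (i in gsel) st$gmeans[i, ] <- st$gmeans[i, ] + tr
    }
  } else if (element$type == "sigma") {
    st$sigma <- state$sigma + stats::runif(1, -mp$sigma_step, mp$sigma_step)
    if (st$sigma < max(system$params$sigma_min, mp$sigma_move_min) ||
        st$sigma > system$params$sigma_max)
      attr(st, "rejected") <- TRUE
  } else if (element$type == "psi") {
    st$psi[element$id] <- state$psi[element$id] +
      stats::runif(1, -mp$psi_step, mp$psi_step)
    if (st$psi[element$id] < mp$psi_min || st$psi[element$id] > mp$psi_max)
      attr(st, "rejected") <- TRUE
  } else stop("unknown element type")
  attr(st, "element") <- element
  st
}

#' Metropolis acceptance rule
#' @param delta score difference (proposed minus current).
#' @param temperature sampling temperature (> 0).
#' @return logical: accept the proposal. `delta <= 0` always accepts.
#' @export
mh_accept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  if (delta <= 0) return(TRUE)
  stats::runif(1) < exp(-delta / temperature)
}

#' One Metropolis Monte Carlo step
#'
#' Proposes a move of one element and accepts it with probability
#' `min(1, exp(-delta/T))`.
#'
#' @param state a [model_state()]; may carry a cached `score` element.
#' @param system an [assembly_system()].
#' @param temperature sampling temperature.
#' @param element,mp passed to [propose_move()].
#' @return the new state with an up-to-date `score` breakdown cached.
#' @export
metropolis_step <- function(state, system, temperature = 1, element = NULL,
                            mp = move_params()) {
  if (is.null(state$score)) state$score <- total_score(state, system)
  prop <- propose_move(state, system, element, mp)
  if (isTRUE(attr(prop, "rejected"))) return(state)
  sc <- total_score(prop, system)
  if (mh_accept(sc$total - state$score$total, temperature)) {
    prop$score <- sc
    attr(prop, "element") <- NULL
    return(prop)
  }
  state
}

#' Geometric replica temperature ladder
#'
#' @param n_replicas replica count.
#' @param t_min,t_max lowest and highest temperatures (defaults 1.0 and
#'   2.5). Spacing is geometric; the production-scale ladder (64 replicas) and
#'   desk-scale ladders are both reachable.
#' @return ascending numeric vector of temperatures.
#' @export
replica_ladder <- function(n_replicas = 8, t_min = 1.0, t_max = 2.5) {
  stopifnot(n_replicas >= 1, t_min > 0, t_max >= t_min)
  if (n_replicas == 1L) return(t_min)
  exp(seq(log(t_min), log(t_max), length.out = n_replicas))
}

# random initial configuration: rigid bodies randomly rotated and placed,
# flexible beads scattered, inside the given box
.randomize_state <- function(state, system, box_lo, box_hi) {
  mob <- mobile_elements(system)
  g <- system$gaussians
  for (id in mob$rigid) {
    mem <- which(!is.na(system$beads$rigid_id) & system$beads$rigid_id == id)
    ctr <- colMeans(state$coords[mem, , drop = FALSE])
    R <- .random_rotation(pi)
    pos <- stats::runif(3, box_lo, box_hi)
    state$coords[mem, ] <- t(R %*% (t(state$coords[mem, , drop = FALSE]) - ctr) + pos)
    if (!is.null(g)) {
      gsel <- which(!is.na(g$rigid_id) & g$rigid_id == id)
      for (i in gsel) {
        state$gmeans[i, ] <- as.numeric(R %*% (state$gmeans[i, ] - ctr) + pos)
        state$gcovs[i, , ] <- R %*% state$gcovs[i, , ] %*% t(R)
      }
    }
  }
  for (bidx in mob$flexible) {
    pos <- stats::runif(3, box_lo, box_hi)
    state$coords[bidx, ] <- pos
    if (!is.null(g)) {
      gsel <- which(!is.na(g$bead) & g$bead == bidx)
      for (i in gsel) state$gmeans[i, ] <- pos
    }
  }
  state
}

#' Sampling box for random initialization
#'
#' The bounding box of the data density means (or of the fixed beads when
#' there is no density), inflated by `pad` Angstrom.
#' @param system an [assembly_system()].
#' @param pad inflation in Angstrom (default 20).
#' @return list with `lo` and `hi` corners.
#' @export
sampling_box <- function(system, pad = 20) {
  if (!is.null(system$data_gmm)) {
    pts <- do.call(rbind, lapply(system$data_gmm, function(g) g$means))
  } else {
    pts <- as.matrix(system$beads[, c("x", "y", "z")])
  }
  list(lo = apply(pts, 2, min) - pad, hi = apply(pts, 2, max) + pad)
}

#' Replica-exchange Gibbs sampling
#'
#' Runs `n_runs` independent replica-exchange calculations. Each Gibbs
#' sweep moves every mobile rigid body and flexible bead once by
#' Metropolis, then updates sigma and the per-class psi values; adjacent
#' replicas attempt an exchange once per sweep (alternating odd/even
#' pairs, standard criterion). Every run starts from an independent random
#' configuration inside the sampling box; frames of the lowest-temperature
#' replica are saved every `save_interval` sweeps. Fully reproducible
#' given `seed`; with a single replica the procedure is plain Metropolis
#' sampling.
#'
#' @param system an [assembly_system()].
#' @param n_sweeps Gibbs sweeps per run.
#' @param n_runs independent runs.
#' @param temperatures ascending ladder (see [replica_ladder()]).
#' @param seed integer seed (one stream drives all runs).
#' @param save_interval sweeps between saved frames (default 10).
#' @param state0 optional common starting state; default [model_state()]
#'   randomized per replica.
#' @param randomize randomize initial configurations (default TRUE).
#' @param mp a [move_params()] list.
#' @return list of trajectories, one per run: `frames` (n_beads x 3 x
#'   n_frames array), `scores` (per-frame breakdown data.frame), `sigma`,
#'   `psi` (n_frames x classes), `swap_rate`, `run`.
#' @export
run_replica_exchange <- function(system, n_sweeps = 5000, n_runs = 4,
                                 temperatures = replica_ladder(8),
                                 seed = NULL, save_interval = 10,
                                 state0 = NULL, randomize = TRUE,
                                 mp = move_params()) {
  stopifnot(n_sweeps >= 1, all(diff(temperatures) > 0) || length(temperatures) == 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0)) state0 <- model_state(system)
  box <- sampling_box(system)
  cs <- .compile_system(system)
  lapply(seq_len(n_runs), function(run) {
    reps <- lapply(seq_along(temperatures), function(i) {
      st <- state0
      if (randomize) st <- .randomize_state(st, system, box$lo, box$hi)
      st
    })
    out <- ia_run_re(cs, lapply(reps, .compile_state, system = system),
                     as.numeric(temperatures), as.integer(n_sweeps),
                     as.integer(save_interval), .compile_moves(mp, system))
    .unpack_trajectory(out, system, run)
  })
}

#' Plain Metropolis sampling (single replica)
#' @inheritParams run_replica_exchange
#' @param temperature single sampling temperature.
#' @return a single trajectory (see [run_replica_exchange()]).
#' @export
run_metropolis <- function(system, n_sweeps = 5000, temperature = 1,
                           seed = NULL, save_interval = 10, state0 = NULL,
                           randomize = TRUE, mp = move_params()) {
  run_replica_exchange(system, n_sweeps = n_sweeps, n_runs = 1,
                       temperatures = temperature, seed = seed,
                       save_interval = save_interval, state0 = state0,
                       randomize = randomize, mp = mp)[[1]]
}

# ---- compiled (flat) forms handed to the C++ sweep loop ----

.compile_system <- function(system) {
  b <- system$beads
  n <- nrow(b)
  rigid_id <- ifelse(is.na(b$rigid_id), 0L, as.integer(b$rigid_id))
  mob <- mobile_elements(system)
  g <- system$gaussians
  modules <- if (is.null(system$data_gmm)) character(0) else names(system$data_gmm)
  xl <- system$crosslinks
  classes <- c("intra_module", "inter_module")
  th <- system$tethers
  p <- system$params
  list(
    n_beads = as.integer(n),
    radius = as.numeric(b$radius),
    is_coarse = as.integer(b$scale != "fine"),
    rigid_id = rigid_id,
    mobile_rigid = as.integer(mob$rigid),
    mobile_flex = as.integer(mob$flexible),
    g_n = if (is.null(g)) 0L else length(g$gmm$weights),
    g_w = if (is.null(g)) numeric(0) else as.numeric(g$gmm$weights),
    g_rigid = if (is.null(g)) integer(0) else ifelse(is.na(g$rigid_id), 0L, as.integer(g$rigid_id)),
    g_bead = if (is.null(g)) integer(0) else ifelse(is.na(g$bead), 0L, as.integer(g$bead)),
    g_module = if (is.null(g)) integer(0) else match(g$module, modules),
    n_modules = length(modules),
    d_w = if (is.null(system$data_gmm)) numeric(0) else unlist(lapply(system$data_gmm, function(x) x$weights)),
    d_means = if (is.null(system$data_gmm)) matrix(0, 0, 3) else do.call(rbind, lapply(system$data_gmm, function(x) x$means)),
    d_covs = if (is.null(system$data_gmm)) matrix(0, 0, 9) else do.call(rbind, lapply(system$data_gmm, function(x) t(apply(x$covs, 1, identity)))),
    d_module = if (is.null(system$data_gmm)) integer(0) else rep(seq_along(modules), vapply(system$data_gmm, function(x) length(x$weights), integer(1))),
    xl_n = if (is.null(xl)) 0L else nrow(xl),
    xl_b1 = if (is.null(xl)) integer(0) else as.integer(xl$bead1),
    xl_b2 = if (is.null(xl)) integer(0) else as.integer(xl$bead2),
    xl_w = if (is.null(xl)) numeric(0) else redundancy_weight(xl$n_spectra, p$redundancy_cap),
    xl_class = if (is.null(xl)) integer(0) else match(xl$xl_class, classes),
    conn = if (nrow(system$conn_pairs)) cbind(system$conn_pairs,
      p$connectivity_factor * (b$radius[system$conn_pairs[, 1]] + b$radius[system$conn_pairs[, 2]])) else matrix(0, 0, 3),
    teth = if (is.null(th)) matrix(0, 0, 5) else cbind(th$bead, th$x, th$y, th$z, th$k),
    l_xl = p$l_xl, slope = p$slope, em_scale = p$em_scale,
    k_ev = p$k_excluded, k_conn = p$k_connect,
    sigma_min = p$sigma_min, sigma_max = p$sigma_max
  )
}

.compile_state <- function(state, system) {
  list(coords = state$coords,
       gmeans = if (is.null(state$gmeans)) matrix(0, 0, 3) else state$gmeans,
       gcovs = if (is.null(state$gcovs)) matrix(0, 0, 9) else
         matrix(state$gcovs, nrow = dim(state$gcovs)[1], ncol = 9),
       sigma = state$sigma,
       psi = as.numeric(state$psi[c("intra_module", "inter_module")]))
}

.compile_moves <- function(mp, system) {
  c(rigid_trans = mp$rigid_trans, rigid_rot = mp$rigid_rot,
    flex_trans = mp$flex_trans, sigma_step = mp$sigma_step,
    psi_step = mp$psi_step, psi_min = mp$psi_min, psi_max = mp$psi_max,
    sigma_move_min = max(mp$sigma_move_min, system$params$sigma_min))
}

.unpack_trajectory <- function(out, system, run) {
  nb <- nrow(system$beads)
  nf <- length(out$frames)
  frames <- array(0, dim = c(nb, 3, nf))
  for (i in seq_len(nf)) frames[, , i] <- out$frames[[i]]
  scores <- do.call(rbind, lapply(out$scores, function(s)
    as.data.frame(as.list(s))))
  psi <- do.call(rbind, out$psi)
  colnames(psi) <- c("intra_module", "inter_module")
  list(frames = frames, scores = scores, sigma = as.numeric(out$sigma),
       psi = psi, gmeans = out$gmeans, gcovs = out$gcovs,
       swap_rate = out$swap_rate, run = run)
}

#' Rebuild a [model_state()] from a saved trajectory frame
#' @param traj a trajectory from [run_replica_exchange()].
#' @param i frame index.
#' @param system the [assembly_system()] that produced it.
#' @return a [model_state()].
#' @export
frame_state <- function(traj, i, system) {
  st <- model_state(system, sigma = traj$sigma[i],
                    psi = c(intra_module = unname(traj$psi[i, 1]),
                            inter_module = unname(traj$psi[i, 2])))
  st$coords <- traj$frames[, , i]
  if (!is.null(st$gmeans)) {
    st$gmeans <- traj$gmeans[[i]]
    gc <- traj$gcovs[[i]]
    st$gcovs <- array(gc, dim = c(nrow(gc), 3, 3))
  }
  st
}
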