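#' Topology configuration
#'
#' Declares, for every subunit, its residue-range segmentation: the module
#' each range belongs to, the rigid body (if any) it is part of, the source
#' structure/chain providing coordinates, and whether the segment is fixed
#' during sampling. Ranges within a subunit must be disjoint and together
#' cover residues 1..length exactly; every residue must carry a module label.
#'
#' @param subunits list of subunit entries. Each entry is a list with
#'   `name`, `length`, and `segments`: a list of segments, each with
#'   `range` (length-2 integer, inclusive), `module`, and optionally
#'   `rigid_body` (integer id; absent/NULL means flexible), `structure`,
#'   `chain`, `fixed` (logical, default FALSE).
#' @param restraints named list of restraint parameters (see
#'   [restraint_params()]); merged over defaults.
#' @param sampling named list of sampling parameters; merged over defaults.
#' @return object of class `topology_config`.
#' @export
topology_config <- function(subunits, restraints = list(), sampling = list()) {
  names(subunits) <- vapply(subunits, function(s) s$name, character(1))
  for (s in subunits) {
    if (is.null(s$name) || is.null(s$length) || is.null(s$segments))
      stop("each subunit needs 'name', 'length' and 'segments'")
    covered <- integer(0)
    for (seg in s$segments) {
      r <- as.integer(seg$range)
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > s$length)
        stop("bad residue range in subunit ", s$name)
      if (is.null(seg$module)) stop("segment without module label in subunit ", s$name)
      rng <- seq(r[1], r[2])
      if (length(intersect(covered, rng)))
        stop("overlapping residue ranges in subunit ", s$name)
      covered <- c(covered, rng)
    }
    if (length(covered) != s$length)
      stop("residue ranges of subunit ", s$name, " do not cover 1..", s$length)
  }
  structure(list(subunits = subunits,
                 restraints = utils::modifyList(restraint_params(), restraints),
                 sampling = sampling),
            class = "topology_config")
}

#' Read a topology configuration from YAML
#' @param path YAML file path.
#' @return a [topology_config()].
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$subunits)) stop("topology file has no 'subunits' entry")
  topology_config(y$subunits,
                  restraints = if (is.null(y$restraints)) list() else y$restraints,
                  sampling = if (is.null(y$sampling)) list() else y$sampling)
}

#' Write a topology configuration to YAML
#' @param topology a [topology_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "topology_config"))
  yaml::write_yaml(list(subunits = unname(topology$subunits),
                        restraints = topology$restraints,
                        sampling = topology$sampling), path)
  invisible(path)
}

#' Module assignment of specific residues
#'
#' @param topology a [topology_config()].
#' @param protein character vector of subunit names.
#' @param residue integer vector of 1-based residue indices.
#' @return character vector of module labels.
#' @export
module_of <- function(topology, protein, residue) {
  n <- max(length(protein), length(residue))
  protein <- rep_len(protein, n)
  residue <- rep_len(residue, n)
  out <- character(n)
  for (i in seq_along(protein)) {
    s <- topology$subunits[[protein[i]]]
    if (is.null(s)) stop("unknown subunit: ", protein[i])
    hit <- NA_character_
    for (seg in s$segments) {
      if (residue[i] >= seg$range[1] && residue[i] <= seg$range[2]) {
        hit <- seg$module
        break
      }
    }
    if (is.na(hit))
      stop("residue outside any declared range: ", protein[i], ":", residue[i])
    out[i] <- hit
  }
  out
}
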