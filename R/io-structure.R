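#' Atomic model of one or more chains
#'
#' Holds per-atom records plus a per-residue Calpha table used by the
#' coarse-graining routines. Residue numbering is 1-based per chain;
#' residues absent from the coordinate file (chain gaps) are recorded in
#' `$missing`, never fabricated.
#'
#' @param atoms data.frame with columns `chain`, `resid` (1-based residue
#'   index), `elety` (atom name), `x`, `y`, `z` (Angstrom), `mass` (Da).
#' @return object of class `atomic_model` with elements `atoms`, `calpha`
#'   (one row per residue: chain, resid, x, y, z, mass = summed atom mass)
#'   and `missing` (chain, resid of flagged gaps).
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "resid", "elety", "x", "y", "z", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  ca <- atoms[atoms$elety == "CA", c("chain", "resid", "x", "y", "z")]
  rmass <- stats::aggregate(mass ~ chain + resid, data = atoms, FUN = sum)
  ca <- merge(ca, rmass, by = c("chain", "resid"), sort = FALSE)
  ca <- ca[order(ca$chain, ca$resid), ]
  rownames(ca) <- NULL
  gaps <- do.call(rbind, lapply(split(ca, ca$chain), function(ch) {
    if (any(diff(ch$resid) <= 0)) stop("residue indices must be strictly increasing within a chain")
    want <- seq(min(ch$resid), max(ch$resid))
    absent <- setdiff(want, ch$resid)
    if (length(absent) == 0L) return(NULL)
    data.frame(chain = ch$chain[1], resid = absent, stringsAsFactors = FALSE)
  }))
  if (is.null(gaps)) gaps <- data.frame(chain = character(), resid = integer())
  rownames(gaps) <- NULL
  structure(list(atoms = atoms, calpha = ca, missing = gaps),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d chain(s), %d residues, %d atoms, %d missing residue(s)\n",
              length(unique(x$calpha$chain)), nrow(x$calpha), nrow(x$atoms),
              nrow(x$missing)))
  invisible(x)
}

# approximate atomic masses for the elements found in proteins
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

.mass_from_elety <- function(elety) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
  el[toupper(elety) %in% c("SE", "SD", "SG")] <- "S"
  m <- .element_mass[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Read a structure file into an [atomic_model()]
#'
#' PDB and mmCIF files are parsed with bio3d. Only the first model of
#' multi-model files is used; heteroatoms are dropped. Per-atom masses are
#' assigned from the element inferred from the atom name.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param chains optional character vector of chain identifiers to keep;
#'   an error is raised if a requested chain is absent.
#' @return an [atomic_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chains = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(at$chain))
    if (length(absent))
      stop("chain(s) absent from file: ", paste(absent, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resid = as.integer(at$resno),
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      mass = .mass_from_elety(at$elety),
                      stringsAsFactors = FALSE)
  atomic_model(atoms)
}

#' Write an [atomic_model()] as a PDB file
#'
#' Minimal ATOM-record writer (coordinates at the PDB's native 1e-3 A
#' precision); used by the synthetic-assembly generator to emit fixtures
#' readable by any standard PDB parser.
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  at <- model$atoms
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   seq_len(nrow(at)),
                   ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
                   "ALA", at$chain, at$resid, at$x, at$y, at$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
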