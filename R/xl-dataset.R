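#' Filter cross-link spectral matches
#'
#' Applies the search-engine quality thresholds, the minimum peptide length,
#' and the classifier ambiguity rule. A spectrum with multiple candidate
#' cross-linked peptide pairs is uniquely assigned to its top-scoring
#' candidate only when the runner-up decision value is more than
#' `ambiguity_gap` units lower; conflicts within the gap are resolved in
#' favor of intra-protein over inter-protein interpretations when that
#' preference is decisive, otherwise the spectrum is flagged ambiguous.
#' Decoy matches are retained (still flagged) for FDR estimation and are
#' removed only at reporting stage. Site-ambiguous residue positions
#' (semicolon lists in `residue1`/`residue2`) are kept with all candidate
#' sites.
#'
#' @param csms CSM data.frame (see [read_csm_table()]); required columns:
#'   `spectrum_id`, `protein1`, `protein2`, `peptide1`, `peptide2`,
#'   `classifier_score`, `peptide_score`, `expect_peptide`,
#'   `expect_protein`, `expect_worse`, `score_difference`,
#'   `is_decoy1`, `is_decoy2`.
#' @param params named list overriding defaults: `min_peptide_score` (20),
#'   `max_expectation` (50), `min_score_difference` (0),
#'   `min_peptide_length` (4), `ambiguity_gap` (0.3).
#' @return the retained CSM rows with an added logical column `ambiguous`;
#'   attribute `n_removed` records counts per filter.
#' @export
filter_csms <- function(csms, params = list()) {
  p <- utils::modifyList(list(min_peptide_score = 20, max_expectation = 50,
                              min_score_difference = 0, min_peptide_length = 4,
                              ambiguity_gap = 0.3), params)
  need <- c("spectrum_id", "protein1", "protein2", "peptide1", "peptide2",
            "classifier_score", "peptide_score", "expect_peptide",
            "expect_protein", "expect_worse", "score_difference",
            "is_decoy1", "is_decoy2")
  for (col in need)
    if (is.null(csms[[col]])) stop("missing score column: ", col)
  n0 <- nrow(csms)
  keep_scores <- csms$peptide_score >= p$min_peptide_score &
    csms$expect_peptide <= p$max_expectation &
    csms$expect_protein <= p$max_expectation &
    csms$expect_worse <= p$max_expectation &
    csms$score_difference >= p$min_score_difference
  n_score <- sum(!keep_scores)
  keep_len <- nchar(csms$peptide1) >= p$min_peptide_length &
    nchar(csms$peptide2) >= p$min_peptide_length
  n_len <- sum(keep_scores & !keep_len)
  out <- csms[keep_scores & keep_len, , drop = FALSE]

  out$ambiguous <- FALSE
  if (nrow(out)) {
    pick <- unlist(lapply(split(seq_len(nrow(out)), out$spectrum_id), function(i) {
      if (length(i) == 1L) return(i)
      sc <- out$classifier_score[i]
      o <- order(sc, decreasing = TRUE)
      top <- i[o[1]]
      gap <- sc[o[1]] - sc[o[2]]
      if (gap > p$ambiguity_gap) return(top)
      # candidates within the gap of the top match
      cand <- i[sc > sc[o[1]] - p$ambiguity_gap - 1e-12]
      intra <- out$protein1[cand] == out$protein2[cand]
      if (sum(intra) == 1L && !all(intra)) return(cand[intra])
      attr(top, "ambiguous") <- TRUE
      top
    }))
    amb <- vapply(split(seq_len(nrow(out)), out$spectrum_id), function(i) {
      if (length(i) == 1L) return(FALSE)
      sc <- sort(out$classifier_score[i], decreasing = TRUE)
      gap <- sc[1] - sc[2]
      if (gap > p$ambiguity_gap) return(FALSE)
      cand <- i[out$classifier_score[i] > sc[1] - p$ambiguity_gap - 1e-12]
      intra <- out$protein1[cand] == out$protein2[cand]
      !(sum(intra) == 1L && !all(intra))
    }, logical(1))
    out <- out[sort(pick), , drop = FALSE]
    out$ambiguous <- amb[match(out$spectrum_id, names(amb))]
  }
  rownames(out) <- NULL
  attr(out, "n_removed") <- c(scores = n_score, short_peptide = n_len,
                              competing = n0 - n_score - n_len - nrow(out))
  out
}

#' Target-decoy false discovery rate
#'
#' FDR at a classifier threshold is the number of decoy hits at or above the
#' threshold, divided by the decoy/target database size ratio, divided by
#' the number of target hits.
#'
#' @param csms CSM data.frame with `classifier_score`, `is_decoy1`,
#'   `is_decoy2` (a CSM is a decoy match iff either peptide is decoy).
#' @param threshold decision-value acceptance threshold.
#' @param decoy_ratio decoy/target database size ratio (default 10).
#' @return FDR fraction in \[0, 1+\); 0 when there are no decoy hits;
#'   `NA` with a warning when there are no target hits.
#' @export
estimate_fdr <- function(csms, threshold = 0, decoy_ratio = 10) {
  if (decoy_ratio <= 0) stop("'decoy_ratio' must be > 0")
  hit <- csms$classifier_score >= threshold
  dec <- csms$is_decoy1 | csms$is_decoy2
  n_target <- sum(hit & !dec)
  n_decoy <- sum(hit & dec)
  if (n_target == 0L) {
    warning("no target hits at threshold ", threshold, "; FDR undefined")
    return(NA_real_)
  }
  (n_decoy / decoy_ratio) / n_target
}

#' Collapse filtered CSMs to unique cross-links
#'
#' Drops decoy and ambiguous matches, expands site-ambiguous positions
#' (each candidate residue pair receives an equal share of the spectral
#' count), and merges to unique unordered residue pairs.
#'
#' @param csms output of [filter_csms()].
#' @param source dataset label recorded on every link.
#' @return a [crosslink_set()].
#' @export
csms_to_crosslinks <- function(csms, source = "csm") {
  keep <- !(csms$is_decoy1 | csms$is_decoy2) & !csms$ambiguous
  csms <- csms[keep, , drop = FALSE]
  if (nrow(csms) == 0L) return(crosslink_set())
  rows <- lapply(seq_len(nrow(csms)), function(i) {
    r1 <- as.integer(strsplit(as.character(csms$residue1[i]), ";")[[1]])
    r2 <- as.integer(strsplit(as.character(csms$residue2[i]), ";")[[1]])
    g <- expand.grid(residue1 = r1, residue2 = r2)
    data.frame(protein1 = csms$protein1[i], residue1 = g$residue1,
               protein2 = csms$protein2[i], residue2 = g$residue2,
               n_spectra = 1 / nrow(g), source = source,
               stringsAsFactors = FALSE)
  })
  crosslink_set(do.call(rbind, rows))
}

#' Merge cross-link datasets
#'
#' Union under unordered-pair identity: pairs present in both sets appear
#' once, with spectral counts summed and both source labels retained.
#' Merging is commutative and associative.
#'
#' @param a,b [crosslink_set()] objects using the same subunit naming.
#' @return a [crosslink_set()].
#' @export
merge_crosslink_sets <- function(a, b) {
  stopifnot(inherits(a, "crosslink_set"), inherits(b, "crosslink_set"))
  crosslink_set(rbind(as.data.frame(a), as.data.frame(b)))
}

#' Classify cross-links as intra- or inter-module
#'
#' A link is `intra_module` iff both endpoints map to the same module under
#' the topology's per-residue-range module assignment.
#'
#' @param xlset a [crosslink_set()].
#' @param topology a [topology_config()].
#' @return the set with an `xl_class` column (`intra_module`/`inter_module`).
#' @export
classify_crosslinks <- function(xlset, topology) {
  if (nrow(xlset) == 0L) {
    xlset$xl_class <- character(0)
    return(xlset)
  }
  m1 <- module_of(topology, xlset$protein1, xlset$residue1)
  m2 <- module_of(topology, xlset$protein2, xlset$residue2)
  xlset$xl_class <- ifelse(m1 == m2, "intra_module", "inter_module")
  xlset
}

#' Map cross-links onto a known structure
#'
#' Computes the Euclidean Calpha-Calpha distance of every link whose two
#' endpoints are both resolved in the model. Links with an unresolved
#' endpoint are reported unmappable and excluded from the violation
#' denominator.
#'
#' @param xlset a [crosslink_set()]; `protein1`/`protein2` must match chain
#'   identifiers of `model`.
#' @param model an [atomic_model()].
#' @param threshold violation threshold in Angstrom (default 35).
#' @return list with `links` (per-link distance and flags) and `summary`
#'   (mappable count, violation count, fraction, distance histogram).
#' @export
map_crosslinks_to_structure <- function(xlset, model, threshold = 35) {
  ca <- model$calpha
  key <- paste(ca$chain, ca$resid)
  i1 <- match(paste(xlset$protein1, xlset$residue1), key)
  i2 <- match(paste(xlset$protein2, xlset$residue2), key)
  mappable <- !is.na(i1) & !is.na(i2)
  d <- rep(NA_real_, nrow(xlset))
  if (any(mappable)) {
    dx <- ca$x[i1[mappable]] - ca$x[i2[mappable]]
    dy <- ca$y[i1[mappable]] - ca$y[i2[mappable]]
    dz <- ca$z[i1[mappable]] - ca$z[i2[mappable]]
    d[mappable] <- sqrt(dx^2 + dy^2 + dz^2)
  }
  links <- data.frame(as.data.frame(xlset), distance = d,
                      mappable = mappable,
                      violated = !is.na(d) & d > threshold)
  hist_breaks <- seq(0, max(c(d[!is.na(d)], threshold)) + 5, by = 5)
  list(links = links,
       summary = list(n_total = nrow(xlset),
                      n_mappable = sum(mappable),
                      n_violated = sum(links$violated),
                      violated_fraction = if (sum(mappable)) sum(links$violated) / sum(mappable) else NA_real_,
                      threshold = threshold,
                      histogram = if (sum(mappable)) graphics::hist(d[mappable], breaks = hist_breaks, plot = FALSE) else NULL))
}

#' Jackknife a cross-link dataset
#'
#' Removes `floor(fraction * n)` links uniformly at random; reproducible
#' under a fixed RNG state.
#'
#' @param xlset a [crosslink_set()].
#' @param fraction fraction of links to remove (default 0.1).
#' @return a [crosslink_set()] with the remaining links.
#' @export
jackknife_crosslinks <- function(xlset, fraction = 0.1) {
  n <- nrow(xlset)
  n_drop <- floor(fraction * n)
  if (n_drop == 0L) return(xlset)
  drop <- sample.int(n, n_drop)
  out <- xlset[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
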