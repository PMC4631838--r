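#' Cross-link set
#'
#' A table of unique residue-pair restraints. Identity of a cross-link is the
#' unordered pair of (protein, residue) endpoints; duplicate rows are merged
#' with spectral counts summed and source labels combined. Endpoints are
#' stored in canonical order (protein1/residue1 lexicographically first).
#'
#' @param df data.frame with columns `protein1`, `residue1`, `protein2`,
#'   `residue2`, `n_spectra`, `source` (and optionally `xl_class`).
#' @return object of class `crosslink_set` (a data.frame).
#' @export
crosslink_set <- function(df = NULL) {
  cols <- c("protein1", "residue1", "protein2", "residue2", "n_spectra", "source")
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(protein1 = character(), residue1 = integer(),
                     protein2 = character(), residue2 = integer(),
                     n_spectra = numeric(), source = character(),
                     stringsAsFactors = FALSE)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$n_spectra < 0)) stop("negative spectral count")
  df <- .xl_canonicalize(df)
  class(df) <- c("crosslink_set", "data.frame")
  df
}

# order endpoints within a row, then merge duplicate unordered pairs
.xl_canonicalize <- function(df) {
  if (nrow(df) == 0L) return(df)
  df$residue1 <- as.integer(df$residue1)
  df$residue2 <- as.integer(df$residue2)
  k1 <- paste(df$protein1, sprintf("%09d", df$residue1))
  k2 <- paste(df$protein2, sprintf("%09d", df$residue2))
  swap <- k2 < k1
  if (any(swap)) {
    tmp <- df[swap, c("protein1", "residue1")]
    df[swap, c("protein1", "residue1")] <- df[swap, c("protein2", "residue2")]
    df[swap, c("protein2", "residue2")] <- tmp
  }
  key <- paste(df$protein1, df$residue1, df$protein2, df$residue2, sep = "\r")
  if (anyDuplicated(key)) {
    idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
    df <- do.call(rbind, lapply(idx, function(i) {
      r <- df[i[1], , drop = FALSE]
      r$n_spectra <- sum(df$n_spectra[i])
      r$source <- paste(unique(unlist(strsplit(df$source[i], ";", fixed = TRUE))),
                        collapse = ";")
      r
    }))
    rownames(df) <- NULL
  }
  df
}

#' Read a cross-link table (TSV)
#'
#' Expects tab-separated columns `protein1`, `residue1`, `protein2`,
#' `residue2`, `n_spectra`, `source`. Rows with identical unordered
#' endpoint pairs are collapsed, summing spectral counts.
#'
#' @param path file path.
#' @return a [crosslink_set()].
#' @export
read_crosslink_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(crosslink_set())
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("protein1", "residue1", "protein2", "residue2", "n_spectra", "source")
  miss <- setdiff(need, hdr)
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(crosslink_set())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(hdr))) {
    bad <- which(nf != length(hdr))[1]
    stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                 bad + 1L, length(hdr), nf[bad]))
  }
  m <- do.call(rbind, parts)
  colnames(m) <- hdr
  df <- data.frame(m, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("residue1", "residue2", "n_spectra")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed row at line %d: non-numeric '%s'", bad + 1L, col))
    }
    df[[col]] <- v
  }
  if (any(df$n_spectra < 0)) {
    bad <- which(df$n_spectra < 0)[1]
    stop(sprintf("negative spectral count at line %d", bad + 1L))
  }
  crosslink_set(df[need])
}

#' Write a cross-link table (TSV)
#' @param xlset a [crosslink_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(xlset, path) {
  utils::write.table(as.data.frame(xlset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write Gaussian mixtures as plain text
#'
#' One component per line: weight, 3 mean coordinates, and the 6 unique
#' covariance entries in order xx xy xz yy yz zz. Round-trips are lossless
#' to printed precision (17 significant digits).
#'
#' @param gmm a [gmm()].
#' @param path file path.
#' @return `read_gmm` returns a [gmm()]; `write_gmm` returns `path`.
#' @export
write_gmm <- function(gmm, path) {
  stopifnot(inherits(gmm, "gmm"))
  n <- length(gmm$weights)
  rows <- vapply(seq_len(n), function(i) {
    S <- gmm$covs[i, , ]
    paste(format(c(gmm$weights[i], gmm$means[i, ],
                   S[1, 1], S[1, 2], S[1, 3], S[2, 2], S[2, 3], S[3, 3]),
                 digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " ")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vals <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 10L || anyNA(v))
      stop(sprintf("malformed GMM component at line %d", i))
    v
  })
  m <- do.call(rbind, vals)
  covs <- array(0, dim = c(nrow(m), 3, 3))
  for (i in seq_len(nrow(m))) {
    s <- m[i, 5:10]
    covs[i, , ] <- matrix(c(s[1], s[2], s[3],
                            s[2], s[4], s[5],
                            s[3], s[5], s[6]), 3, 3)
  }
  gmm(weights = m[, 1], means = m[, 2:4, drop = FALSE], covs = covs)
}

#' Read/write cross-link spectral match tables (TSV)
#'
#' CSM tables carry one row per candidate interpretation of a spectrum, with
#' the classifier decision value and the auxiliary search-engine scores used
#' by [filter_csms()]. Site-ambiguous residue positions are encoded as
#' semicolon-separated lists in `residue1`/`residue2`.
#'
#' @param path file path.
#' @param csms a CSM data.frame.
#' @return `read_csm_table` returns a data.frame.
#' @export
read_csm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$residue1 <- as.character(df$residue1)
  df$residue2 <- as.character(df$residue2)
  df
}

#' @rdname read_csm_table
#' @export
write_csm_table <- function(csms, path) {
  utils::write.table(csms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
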