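#' Construct a genotype matrix
#'
#' Container for an accessions x markers allele-dosage matrix as produced by
#' array genotyping of (near-)inbred accessions. Dosages count copies of the
#' alternate allele, so entries are 0, 1 or 2; missing calls are `NA`. The
#' per-marker allele frequency `theta` is estimated from the non-missing calls
#' at each marker:
#' \deqn{\theta_l = \frac{\sum_i x_{il}}{2\,n_l}}
#' with the sum and count `n_l` over non-missing dosages only.
#'
#' @param dosages Numeric matrix (accessions in rows, markers in columns) with
#'   entries in \{0, 1, 2\} or `NA`. Row and column names are used as accession
#'   and marker ids; defaults are generated when absent.
#' @param theta Optional per-marker allele frequencies. If `NULL` (the usual
#'   case) they are computed from the non-missing dosages. Supplying `theta`
#'   freezes frequencies estimated on an earlier version of the panel, e.g.
#'   before imputation.
#' @param validate If `TRUE` (default) entries must be 0, 1, 2 or `NA`
#'   (called genotypes); `FALSE` admits fractional dosages in `[0, 2]`, as
#'   produced by mean imputation.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `accession_ids`, `marker_ids` and `theta`.
#' @export
geno_matrix <- function(dosages, theta = NULL, validate = TRUE) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- if (validate) {
    !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  } else {
    !is.na(dosages) & (dosages < 0 | dosages > 2)
  }
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid dosage %g at accession row %d, marker column %d: dosages must be 0, 1, 2 or NA",
      dosages[bad][1], ij[1], ij[2]
    ), call. = FALSE)
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("acc%0*d", nchar(nrow(dosages)), seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("m%0*d", nchar(ncol(dosages)), seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate accession ids: ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(dosages))) {
    stop("duplicate marker ids: ",
         paste(unique(colnames(dosages)[duplicated(colnames(dosages))]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(theta)) theta <- marker_freq(dosages)
  stopifnot(length(theta) == ncol(dosages))
  structure(
    list(
      dosages = dosages,
      accession_ids = rownames(dosages),
      marker_ids = colnames(dosages),
      theta = unname(theta)
    ),
    class = "geno_matrix"
  )
}

marker_freq <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  unname(colSums(dosages, na.rm = TRUE) / (2 * pmax(n_obs, 1L)))
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf(
    "<geno_matrix> %d accessions x %d markers (%d missing calls, %.2f%%)\n",
    nrow(x$dosages), ncol(x$dosages), n_miss,
    100 * n_miss / length(x$dosages)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of missing calls per marker and per accession
#'
#' @param g A [geno_matrix()].
#' @return A list with tibbles `by_marker` and `by_accession`.
#' @export
missingness_summary <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  list(
    by_marker = tibble::tibble(
      marker_id = g$marker_ids,
      n_missing = colSums(is.na(g$dosages)),
      missing_frac = colMeans(is.na(g$dosages))
    ),
    by_accession = tibble::tibble(
      accession_id = g$accession_ids,
      n_missing = rowSums(is.na(g$dosages)),
      missing_frac = rowMeans(is.na(g$dosages))
    )
  )
}
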