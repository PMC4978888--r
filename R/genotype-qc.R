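#' Filter markers on missingness and minor-allele frequency
#'
#' Removes markers with a missing-call fraction strictly greater than
#' `max_missing_frac` or a minor-allele frequency strictly below `min_maf`
#' (so markers at exactly either threshold are kept). MAF is
#' `min(theta, 1 - theta)` with `theta` recomputed from the non-missing calls
#' of the input panel.
#'
#' @param g A [geno_matrix()].
#' @param max_missing_frac Markers missing in more than this fraction of
#'   accessions are dropped. Default 0.80.
#' @param min_maf Markers with minor-allele frequency below this are dropped.
#'   Default 0.01.
#' @return A list with `genotypes` (the filtered [geno_matrix()]) and
#'   `removed` (a tibble `marker_id`, `reason`, `missing_frac`, `maf`;
#'   markers failing both filters are reported once with reason
#'   `"missingness"`).
#' @export
filter_markers <- function(g, max_missing_frac = 0.80, min_maf = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  if (max_missing_frac < 0 || max_missing_frac > 1 || min_maf < 0 || min_maf > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  miss <- colMeans(is.na(g$dosages))
  theta <- marker_freq(g$dosages)
  # markers with zero non-missing calls have undefined frequency; treat as
  # fully missing so the missingness rule disposes of them
  all_missing <- colSums(!is.na(g$dosages)) == 0
  maf <- pmin(theta, 1 - theta)
  maf[all_missing] <- NA_real_

  drop_miss <- miss > max_missing_frac | all_missing
  drop_maf <- !drop_miss & maf < min_maf
  keep <- !(drop_miss | drop_maf)
  if (!any(keep)) stop("empty panel: all markers removed by QC", call. = FALSE)

  removed <- tibble::tibble(
    marker_id = unname(g$marker_ids[!keep]),
    reason = unname(ifelse(drop_miss[!keep], "missingness", "maf")),
    missing_frac = unname(miss[!keep]),
    maf = unname(maf[!keep])
  )
  list(
    genotypes = geno_matrix(g$dosages[, keep, drop = FALSE]),
    removed = removed
  )
}

#' Impute missing dosages to the marker mean
#'
#' Every missing call at marker `l` is replaced by `2 * theta_l`, the mean
#' dosage under the marker's estimated allele frequency; non-missing calls are
#' untouched, so the per-marker frequency is preserved exactly. The imputed
#' panel carries the pre-imputation `theta`, which is the frequency the
#' genomic relationship matrix uses downstream.
#'
#' @param g A [geno_matrix()] (normally the output of [filter_markers()]).
#' @return A [geno_matrix()] with no missing cells.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  no_calls <- colSums(!is.na(g$dosages)) == 0
  if (any(no_calls)) {
    stop("marker(s) with zero non-missing calls (run filter_markers first): ",
         paste(utils::head(g$marker_ids[no_calls], 5), collapse = ", "),
         call. = FALSE)
  }
  dos <- g$dosages
  theta <- marker_freq(dos)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- 2 * theta[idx[, 2]]
  geno_matrix(dos, theta = theta, validate = FALSE)
}
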