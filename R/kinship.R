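#' Construct a kinship (genomic relationship) matrix object
#'
#' @param G Symmetric numeric matrix with accession ids as dimnames.
#' @param p_markers Number of markers the matrix was computed from.
#' @return An object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(G, p_markers = NA_integer_) {
  if (!is.matrix(G)) G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("kinship matrix must be square", call. = FALSE)
  if (is.null(rownames(G))) stop("kinship matrix needs accession ids as dimnames",
                                 call. = FALSE)
  if (!all(is.finite(G))) stop("kinship matrix has non-finite entries", call. = FALSE)
  if (max(abs(G - t(G))) > 1e-10) {
    stop("kinship matrix not symmetric (tolerance 1e-10)", call. = FALSE)
  }
  G <- (G + t(G)) / 2
  structure(
    list(accession_ids = rownames(G), G = G, p_markers = p_markers),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d accessions (from %s markers), mean diag %.3f\n",
              nrow(x$G), format(x$p_markers), mean(diag(x$G))))
  invisible(x)
}

#' Compute the genomic relationship matrix
#'
#' Per-marker standardized GRM:
#' \deqn{G_{ii'} = \frac{1}{p} \sum_{l=1}^{p}
#'       \frac{(x_{il} - 2\theta_l)(x_{i'l} - 2\theta_l)}{2\theta_l(1-\theta_l)}}
#' where `x` are allele dosages and `theta_l` the allele frequency carried by
#' the genotype panel. Each marker is centered by its mean dosage and scaled by
#' its binomial variance before averaging, so every marker contributes equally
#' regardless of frequency. When `theta` is the in-sample frequency every row
#' of G sums to zero (the centered scores sum to zero across accessions), and
#' for a fully inbred panel the expected diagonal is 2.
#'
#' @param g A [geno_matrix()] with no missing calls (run [impute_missing()]
#'   first) and frequencies strictly inside (0, 1) (run [filter_markers()]).
#' @return A [kinship_matrix()].
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$dosages)) {
    stop("genotypes contain missing calls; impute_missing() first", call. = FALSE)
  }
  theta <- g$theta
  degenerate <- theta <= 0 | theta >= 1
  if (any(degenerate)) {
    stop("monomorphic marker(s) give division by zero in GRM scaling: ",
         paste(utils::head(g$marker_ids[degenerate], 5), collapse = ", "),
         "; apply filter_markers() first", call. = FALSE)
  }
  W <- sweep(g$dosages, 2, 2 * theta, "-")
  W <- sweep(W, 2, sqrt(2 * theta * (1 - theta)), "/")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(g$accession_ids, g$accession_ids)
  kinship_matrix(G, p_markers = ncol(W))
}

#' Centered, standardized marker scores
#'
#' The matrix `W` with `W[i, l] = (x_il - 2 theta_l) / sqrt(2 theta_l (1 -
#' theta_l))`, such that `compute_grm(g)$G == tcrossprod(W) / p`. Used by the
#' marker-effect models and by the ridge-regression equivalence between G-BLUP
#' and marker BLUP.
#'
#' @param g A [geno_matrix()] without missing calls.
#' @return Numeric matrix with accession ids as rownames.
#' @export
standardized_scores <- function(g) {
  stopifnot(inherits(g, "geno_matrix"), !anyNA(g$dosages))
  theta <- g$theta
  W <- sweep(g$dosages, 2, 2 * theta, "-")
  sweep(W, 2, sqrt(2 * theta * (1 - theta)), "/")
}
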