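#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `format = "dosage"` expects a tab-separated
#' table whose first column holds accession ids and whose header row holds
#' marker ids, with allele dosages 0/1/2 and missing calls written `NA`.
#' `format = "vcf"` reads the GT field of a VCF (v4.x) through
#' \pkg{vcfR}; because germplasm accessions are expected to be (near-)fully
#' inbred, heterozygous calls are accepted as dosage 1 and their count is
#' reported in a message.
#'
#' @param path File path.
#' @param format `"dosage"` or `"vcf"`. Defaults to `"vcf"` for `.vcf` /
#'   `.vcf.gz` extensions, `"dosage"` otherwise.
#' @return A [geno_matrix()] with `theta` computed from the non-missing calls.
#' @export
read_genotypes <- function(path, format = c("auto", "dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    dosage = read_dosage_table(path),
    vcf = read_vcf_genotypes(path)
  )
}

read_dosage_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  if (ncol(tab) < 2) {
    stop("malformed dosage table (need accession id column + >=1 marker): ", path,
         call. = FALSE)
  }
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate accession id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  non_numeric <- is.na(mat) & !is.na(as.matrix(tab[, -1, drop = FALSE]))
  if (any(non_numeric)) {
    line <- which(rowSums(non_numeric) > 0)[1] + 1L  # +1 for header line
    stop(sprintf("parse error in %s at line %d: non-numeric dosage", path, line),
         call. = FALSE)
  }
  rownames(mat) <- ids
  geno_matrix(mat)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # strip phasing, map genotype strings to dosages
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% c("1/1", "1")] <- 2
    out
  }
  dos <- apply(gt, 2, code)
  if (is.null(dim(dos))) dos <- matrix(dos, ncol = ncol(gt), dimnames = dimnames(gt))
  dos <- t(dos)  # accessions in rows
  rownames(dos) <- colnames(gt)
  colnames(dos) <- rownames(gt)
  n_het <- sum(dos == 1, na.rm = TRUE)
  if (n_het > 0) {
    message(sprintf(
      "read_genotypes: %d heterozygous calls coded as dosage 1 (accessions assumed inbred)",
      n_het
    ))
  }
  geno_matrix(dos)
}

#' Write and read a genotype dosage table
#'
#' Tab-separated, first column `accession_id`, header row of marker ids,
#' missing calls written `NA`. Round-trips exactly through [read_genotypes()].
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  tab <- data.frame(accession_id = g$accession_ids,
                    g$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype record table
#'
#' Long-format CSV with one row per (accession, trial, trait) record. Required
#' columns: `accession_id`, `trial`, `state`, `maturity_group`, `trait`,
#' `value`. Optional integer columns `lodging` and `shattering` scored 1-5
#' (1 = erect / no shattering).
#'
#' @param path CSV path.
#' @return A tibble, validated by [validate_phenotypes()].
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(ph)
}

#' Validate a phenotype record table
#'
#' Checks the contract all downstream modules rely on: lodging and shattering
#' scores in 1-5 when present, one state per trial, and no duplicated
#' (accession, trial, trait) record.
#'
#' @param ph A data frame of phenotype records.
#' @return `ph` as a tibble (invisibly validated).
#' @export
validate_phenotypes <- function(ph) {
  ph <- tibble::as_tibble(ph)
  required <- c("accession_id", "trial", "state", "maturity_group", "trait", "value")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (sc in intersect(c("lodging", "shattering"), names(ph))) {
    v <- ph[[sc]]
    if (any(!is.na(v) & !(v %in% 1:5))) {
      stop(sc, " scores must be integers 1-5 or NA", call. = FALSE)
    }
  }
  n_states <- ph |>
    dplyr::distinct(.data$trial, .data$state) |>
    dplyr::count(.data$trial)
  if (any(n_states$n > 1)) {
    stop("trial(s) mapped to more than one state: ",
         paste(n_states$trial[n_states$n > 1], collapse = ", "), call. = FALSE)
  }
  dup <- ph |>
    dplyr::count(.data$accession_id, .data$trial, .data$trait) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicated (accession, trial, trait) records, e.g. ",
         dup$accession_id[1], " / ", dup$trial[1], call. = FALSE)
  }
  ph
}

#' Write predictions from a fitted model
#'
#' CSV with columns `accession_id`, `trait`, `prediction`, `phenotyped`
#' (logical flag: did the accession contribute phenotype records to
#' training?). Round-trips losslessly through [read_predictions()].
#'
#' @param fit A `wgr_fit` object or a tibble with the four columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(fit, path) {
  preds <- if (inherits(fit, "wgr_fit")) {
    tibble::tibble(
      accession_id = names(fit$g_hat),
      trait = fit$trait,
      prediction = fit$mu + unname(fit$g_hat),
      phenotyped = names(fit$g_hat) %in% fit$phenotyped_ids
    )
  } else {
    tibble::as_tibble(fit)
  }
  needed <- c("accession_id", "trait", "prediction", "phenotyped")
  if (!all(needed %in% names(preds))) {
    stop("predictions need columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(preds) == 0) warning("writing empty prediction set (header only)")
  readr::write_csv(preds[needed], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    accession_id = readr::col_character(),
                    trait = readr::col_character(),
                    prediction = readr::col_double(),
                    phenotyped = readr::col_logical()
                  ))
}

#' Write and read a genomic relationship matrix
#'
#' Square tab-separated matrix with accession ids in the first row and first
#' column.
#'
#' @param K A [kinship_matrix()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader a
#'   [kinship_matrix()].
#' @export
write_grm <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  tab <- data.frame(accession_id = K$accession_ids, K$G, check.names = FALSE)
  colnames(tab) <- c("accession_id", K$accession_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- ids
  kinship_matrix(G, p_markers = NA_integer_)
}

#' Read a subpopulation membership-probability table
#'
#' CSV with `accession_id` followed by K numeric membership-probability
#' columns (one per subpopulation, as produced by model-based ancestry
#' estimation). Each row must sum to 1 within 1e-8.
#'
#' @param path CSV path.
#' @return A tibble with `accession_id` and probability columns.
#' @export
read_membership <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_membership(m)
}

validate_membership <- function(m) {
  m <- tibble::as_tibble(m)
  if (!"accession_id" %in% names(m)) {
    stop("membership table needs an accession_id column", call. = FALSE)
  }
  probs <- as.matrix(m[setdiff(names(m), "accession_id")])
  if (any(probs < 0)) stop("negative membership probability", call. = FALSE)
  s <- rowSums(probs)
  off <- which(abs(s - 1) > 1e-8)
  if (length(off)) {
    stop("membership probabilities do not sum to 1 for accession(s): ",
         paste(m$accession_id[utils::head(off, 5)], collapse = ", "), call. = FALSE)
  }
  m
}
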