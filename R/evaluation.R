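#' Predictive ability
#'
#' Pearson product-moment correlation between genomic predictions and
#' observed phenotypes (adjusted for trial and maturity-group effects). No
#' correction for the heritability of the validation phenotypes is applied,
#' so values are conservative relative to the correlation with true breeding
#' values.
#'
#' @param pred,obs Paired numeric vectors (one value per accession).
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when either vector
#'   has zero variance.
#' @export
predictive_ability <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  keep <- stats::complete.cases(pred, obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(pred) < 3) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("zero variance in predictions or observations; predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs)
}

#' Bootstrap confidence interval for predictive ability
#'
#' Percentile interval of the Pearson correlation over paired resampling with
#' replacement. Degenerate resamples (zero variance in either vector) are
#' redrawn and their count reported in a message.
#'
#' @param pred,obs Paired numeric vectors.
#' @param reps Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(pred, obs, reps = 10000, level = 0.95, seed = 1L) {
  stopifnot(length(pred) == length(obs), reps >= 1)
  keep <- stats::complete.cases(pred, obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  if (n < 3) stop("need >= 3 pairs", call. = FALSE)
  set.seed(seed)
  rs <- numeric(reps)
  n_redrawn <- 0L
  for (i in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(pred[idx]) > 0 && stats::sd(obs[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100 * reps) stop("cannot draw non-degenerate resample",
                                       call. = FALSE)
    }
    rs[i] <- stats::cor(pred[idx], obs[idx])
  }
  if (n_redrawn > 0) {
    message(sprintf("bootstrap_ci: %d degenerate resample(s) redrawn", n_redrawn))
  }
  a <- (1 - level) / 2
  unname(stats::quantile(rs, c(a, 1 - a), type = 7))
}

#' Reduction in predictive ability after covariate correction
#'
#' Compares two cross-validation reports for the same groups — one fit on the
#' raw trait, one with nuisance covariates (lodging/shattering) removed — and
#' expresses the drop per group as a percentage of the original predictive
#' ability, `100 (r_raw - r_adj) / r_raw`. Groups with non-positive raw
#' predictive ability are flagged `NA` (a percentage of a non-positive base
#' is meaningless).
#'
#' @param report_raw,report_adj `cv_report`s (or tibbles with `group` and `r`)
#'   covering the same groups.
#' @return A tibble `group`, `r_raw`, `r_adj`, `pct_reduction`, with the mean
#'   across defined groups as attribute `"mean_reduction"`.
#' @export
covariate_reduction <- function(report_raw, report_adj) {
  raw <- dplyr::select(tibble::as_tibble(report_raw), "group", r_raw = "r")
  adj <- dplyr::select(tibble::as_tibble(report_adj), "group", r_adj = "r")
  if (!setequal(raw$group, adj$group)) {
    stop("reports cover different groups", call. = FALSE)
  }
  out <- dplyr::inner_join(raw, adj, by = "group") |>
    dplyr::mutate(pct_reduction = dplyr::if_else(
      .data$r_raw > 0, 100 * (.data$r_raw - .data$r_adj) / .data$r_raw, NA_real_
    ))
  if (any(is.na(out$pct_reduction) & !is.na(out$r_raw))) {
    warning("reduction undefined for group(s) with non-positive raw predictive ability")
  }
  attr(out, "mean_reduction") <- mean(out$pct_reduction, na.rm = TRUE)
  out
}

#' Selection enrichment of the top predicted accessions
#'
#' Selects the top `top_frac` of accessions on their genomic predictions
#' (ties broken by stable input order) and reports the percentage of the
#' selected set whose observed phenotype beats the observed mean, and the
#' percentage falling in the observed bottom decile (at or below the
#' empirical `top_frac` quantile, type 7). With perfect predictions these are
#' (100, 0); with uninformative predictions they approach (50, 10).
#'
#' @param pred,obs Paired numeric vectors over at least 10 accessions.
#' @param top_frac Selected fraction (default 0.10); `ceiling(top_frac * n)`
#'   accessions are selected, and the same fraction defines the bottom
#'   quantile of the observations.
#' @return A tibble with `n_selected`, `pct_gt_mean`, `pct_bottom`.
#' @export
enrichment <- function(pred, obs, top_frac = 0.10) {
  stopifnot(length(pred) == length(obs))
  keep <- stats::complete.cases(pred, obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  if (n < 10) stop("enrichment undefined: need >= 10 accessions", call. = FALSE)
  n_sel <- ceiling(top_frac * n)
  sel <- order(pred, decreasing = TRUE)[seq_len(n_sel)]
  cut_low <- stats::quantile(obs, top_frac, type = 7)
  tibble::tibble(
    n_selected = n_sel,
    pct_gt_mean = 100 * mean(obs[sel] > mean(obs)),
    pct_bottom = 100 * mean(obs[sel] <= cut_low)
  )
}

#' Per-group enrichment from cross-validation predictions
#'
#' Applies [enrichment()] separately to each group of a [run_scheme()]
#' report's attached predictions, mirroring how selections would be checked
#' against each field trial.
#'
#' @param report A `cv_report` from [run_scheme()].
#' @param top_frac Selected fraction.
#' @return A tibble with one row per group plus a `"Mean"` row.
#' @export
enrichment_by_group <- function(report, top_frac = 0.10) {
  preds <- attr(report, "predictions")
  if (is.null(preds)) stop("report carries no predictions", call. = FALSE)
  per_group <- preds |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(dplyr::n() >= 10) |>
    dplyr::group_modify(~ enrichment(.x$prediction, .x$obs, top_frac)) |>
    dplyr::ungroup()
  dplyr::bind_rows(
    per_group,
    tibble::tibble(group = "Mean",
                   n_selected = sum(per_group$n_selected),
                   pct_gt_mean = mean(per_group$pct_gt_mean),
                   pct_bottom = mean(per_group$pct_bottom))
  )
}
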