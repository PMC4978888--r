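#' Fit the trial and maturity-group fixed-effect structure
#'
#' Ordinary least-squares fit of the nongenetic part of the record-level
#' linear predictor
#' \deqn{y_{ijk} = \mu + e_j + m_{k(j)} + \dots + \varepsilon_{ijk}}
#' where `e_j` is the effect of trial `j` and `m_{k(j)}` the effect of
#' maturity group `k` nested within trial `j` (maturity adaptation depends on
#' trial latitude, so MG effects are never shared across trials). Optional
#' lodging and/or shattering scores enter as fixed covariates. Identifiability
#' uses sum-to-zero constraints: the trial effects average to zero over
#' trials, and within each trial the MG effects average to zero over that
#' trial's observed MG cells; any full-rank constraint yields the same
#' adjusted phenotypes, which is what downstream consumes.
#'
#' @param ph Phenotype record tibble (see [read_phenotypes()]).
#' @param trait Trait name to model (`ph` is filtered to it).
#' @param covariates Character subset of `c("lodging", "shattering")` to fit
#'   as fixed covariates; records missing a used covariate are dropped with a
#'   message.
#' @return An object of class `fixed_design` with elements `mu`,
#'   `trial_effects`, `mg_effects`, `covariate_coefs`, `sigma2_eps`, plus the
#'   per-cell fitted values used by [adjust_phenotypes()].
#' @export
fit_fixed_effects <- function(ph, trait, covariates = character()) {
  ph <- validate_phenotypes(ph)
  stopifnot(all(covariates %in% c("lodging", "shattering")))
  dat <- dplyr::filter(ph, .data$trait == !!trait)
  if (nrow(dat) == 0) stop("no records for trait ", trait, call. = FALSE)
  if (length(covariates)) {
    missing_cols <- setdiff(covariates, names(dat))
    if (length(missing_cols)) {
      stop("covariate column(s) absent: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    ok <- stats::complete.cases(dat[covariates])
    if (any(!ok)) {
      message(sprintf("fit_fixed_effects: dropping %d record(s) lacking covariate scores",
                      sum(!ok)))
      dat <- dat[ok, , drop = FALSE]
    }
    if (nrow(dat) == 0) stop("no records with complete covariates", call. = FALSE)
  }
  dat$.cell <- interaction(dat$trial, dat$maturity_group, drop = TRUE, sep = "\r")

  single_cell <- nlevels(dat$.cell) == 1
  form <- stats::as.formula(paste(
    if (single_cell) "value ~ 1" else "value ~ 0 + .cell",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))
  fit <- stats::lm(form, data = dat)
  co <- stats::coef(fit)
  if (single_cell) {
    names(co)[names(co) == "(Intercept)"] <- paste0(".cell", levels(dat$.cell))
  }
  if (anyNA(co)) {
    stop("rank-deficient fixed-effect design; aliased terms: ",
         paste(gsub("\r", ":", names(co)[is.na(co)]), collapse = ", "),
         call. = FALSE)
  }
  cell_idx <- grepl("^\\.cell", names(co))
  cell_fit <- tibble::tibble(
    cell = sub("^\\.cell", "", names(co)[cell_idx]),
    fit = unname(co[cell_idx])
  ) |>
    tidyr::separate(.data$cell, into = c("trial", "maturity_group"), sep = "\r")

  # sum-to-zero decomposition: trial effect = unweighted mean of that trial's
  # cell intercepts minus the grand mean of trial means
  trial_means <- cell_fit |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(trial_mean = mean(.data$fit), .groups = "drop")
  mu <- mean(trial_means$trial_mean)
  trial_effects <- dplyr::mutate(trial_means, effect = .data$trial_mean - mu) |>
    dplyr::select("trial", "effect")
  mg_effects <- cell_fit |>
    dplyr::left_join(trial_means, by = "trial") |>
    dplyr::mutate(effect = .data$fit - .data$trial_mean) |>
    dplyr::select("trial", "maturity_group", "effect")

  covariate_coefs <- if (length(covariates)) co[covariates] else stats::setNames(numeric(0), character(0))

  structure(
    list(
      trait = trait,
      covariates = covariates,
      mu = mu,
      trial_effects = trial_effects,
      mg_effects = mg_effects,
      covariate_coefs = covariate_coefs,
      sigma2_eps = summary(fit)$sigma^2,
      cell_fit = dplyr::select(cell_fit, "trial", "maturity_group", "fit"),
      n_records = nrow(dat)
    ),
    class = "fixed_design"
  )
}

#' @export
print.fixed_design <- function(x, ...) {
  cat(sprintf(
    "<fixed_design> trait %s: mu = %.4g, %d trials, %d (trial, MG) cells%s\n",
    x$trait, x$mu, nrow(x$trial_effects), nrow(x$mg_effects),
    if (length(x$covariates)) paste0(", covariates: ", paste(x$covariates, collapse = "+")) else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fixed-effect design
#'
#' @param x A `fixed_design`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `level`, `estimate`.
#' @method tidy fixed_design
#' @export
tidy.fixed_design <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "mu", level = NA_character_, estimate = x$mu),
    tibble::tibble(term = "trial", level = x$trial_effects$trial,
                   estimate = x$trial_effects$effect),
    tibble::tibble(term = "mg_within_trial",
                   level = paste(x$mg_effects$trial, x$mg_effects$maturity_group, sep = ":"),
                   estimate = x$mg_effects$effect),
    tibble::tibble(term = "covariate", level = names(x$covariate_coefs),
                   estimate = unname(x$covariate_coefs))
  )
}

#' Adjust phenotypes for trial and maturity-group effects
#'
#' Subtracts the fitted fixed part (minus the grand mean) from every record:
#' `y_adj = y - (cell fit + covariate terms) + mu`. The per-accession
#' aggregate is the mean of the accession's adjusted records, and is the
#' response the whole-genome regression models train on as well as the
#' observation predictive ability is computed against.
#'
#' @param ph Phenotype record tibble.
#' @param design A [fit_fixed_effects()] result for the same trait.
#' @return A list of class `adjusted_phenotypes`: `records` (the input rows
#'   for the trait with an added `value_adj` column) and `by_accession`
#'   (tibble `accession_id`, `value_adj`, `n_records`).
#' @export
adjust_phenotypes <- function(ph, design) {
  stopifnot(inherits(design, "fixed_design"))
  ph <- validate_phenotypes(ph)
  dat <- dplyr::filter(ph, .data$trait == !!design$trait)
  if (length(design$covariates)) {
    ok <- stats::complete.cases(dat[design$covariates])
    if (any(!ok)) {
      message(sprintf("adjust_phenotypes: dropping %d record(s) lacking covariate scores",
                      sum(!ok)))
      dat <- dat[ok, , drop = FALSE]
    }
  }
  dat <- dat |>
    dplyr::mutate(maturity_group = as.character(.data$maturity_group),
                  trial = as.character(.data$trial)) |>
    dplyr::left_join(
      dplyr::mutate(design$cell_fit,
                    trial = as.character(.data$trial),
                    maturity_group = as.character(.data$maturity_group)),
      by = c("trial", "maturity_group")
    )
  if (anyNA(dat$fit)) {
    bad <- dat[is.na(dat$fit), c("trial", "maturity_group")]
    stop("record(s) from (trial, MG) cell(s) unseen by the design: ",
         paste(utils::head(unique(paste(bad$trial, bad$maturity_group, sep = ":")), 5),
               collapse = ", "), call. = FALSE)
  }
  cov_part <- rep(0, nrow(dat))
  for (cv in design$covariates) {
    cov_part <- cov_part + design$covariate_coefs[[cv]] * dat[[cv]]
  }
  dat$value_adj <- dat$value - (dat$fit + cov_part) + design$mu
  dat$fit <- NULL
  by_accession <- dat |>
    dplyr::group_by(.data$accession_id) |>
    dplyr::summarise(value_adj = mean(.data$value_adj),
                     n_records = dplyr::n(), .groups = "drop")
  structure(list(records = tibble::as_tibble(dat), by_accession = by_accession,
                 trait = design$trait, mu = design$mu),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf("<adjusted_phenotypes> trait %s: %d records on %d accessions\n",
              x$trait, nrow(x$records), nrow(x$by_accession)))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' For a single replicated trial laid out in complete blocks, fits the model
#' with replicate as a fixed effect and accession as a random effect, and
#' returns
#' \deqn{H^2 = \hat\sigma^2_A / (\hat\sigma^2_A + \hat\sigma^2_\varepsilon / r)}
#' where `r` is the harmonic mean number of replicates per accession.
#' Variance components come from REML (\pkg{lme4}); if the REML fit fails, a
#' method-of-moments ANOVA estimator is used, with negative accession-variance
#' estimates truncated at zero.
#'
#' @param ph Records of one trial with columns `accession_id`, `rep`, `value`
#'   (and optionally `trait`, filtered by the `trait` argument).
#' @param trait Optional trait name to filter on.
#' @return `H^2` in `[0, 1]`, with attributes `sigma2_A`, `sigma2_eps`, `r`.
#' @export
entry_mean_heritability <- function(ph, trait = NULL) {
  ph <- tibble::as_tibble(ph)
  if (!is.null(trait) && "trait" %in% names(ph)) {
    ph <- dplyr::filter(ph, .data$trait == !!trait)
  }
  stopifnot(all(c("accession_id", "rep", "value") %in% names(ph)))
  if (dplyr::n_distinct(ph$rep) < 2) {
    stop("heritability undefined on entry-mean basis: need >= 2 reps", call. = FALSE)
  }
  if (dplyr::n_distinct(ph$accession_id) < 2) {
    stop("need >= 2 accessions", call. = FALSE)
  }
  rep_counts <- dplyr::count(ph, .data$accession_id)$n
  r <- length(rep_counts) / sum(1 / rep_counts)  # harmonic mean

  vc <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ factor(rep) + (1 | accession_id), data = ph, REML = TRUE)
    ))
    v <- as.data.frame(lme4::VarCorr(fit))
    c(A = v$vcov[v$grp == "accession_id"], eps = v$vcov[v$grp == "Residual"])
  }, error = function(e) {
    # method-of-moments from the two-way ANOVA mean squares
    a <- stats::anova(stats::aov(value ~ factor(rep) + factor(accession_id), data = ph))
    ms_acc <- a["factor(accession_id)", "Mean Sq"]
    ms_err <- if ("Residuals" %in% rownames(a)) a["Residuals", "Mean Sq"] else 0
    if (is.na(ms_err)) ms_err <- 0
    c(A = max((ms_acc - ms_err) / r, 0), eps = ms_err)
  })
  sigma2_A <- max(vc[["A"]], 0)
  sigma2_eps <- max(vc[["eps"]], 0)
  denom <- sigma2_A + sigma2_eps / r
  H2 <- if (denom == 0) 0 else sigma2_A / denom
  structure(H2, sigma2_A = sigma2_A, sigma2_eps = sigma2_eps, r = r)
}
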