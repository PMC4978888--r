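#' Assign accessions to genetic clusters from membership probabilities
#'
#' Each accession goes to the subpopulation it has the highest membership
#' probability of belonging to; exact ties go to the lowest-numbered cluster
#' and are reported in a message.
#'
#' @param membership Tibble with `accession_id` and one numeric probability
#'   column per cluster (rows summing to 1).
#' @return A tibble `accession_id`, `group` (cluster column name) of class
#'   `cv_grouping` with attribute `criterion = "cluster"`.
#' @export
assign_clusters <- function(membership) {
  m <- validate_membership(membership)
  prob_cols <- setdiff(names(m), "accession_id")
  probs <- as.matrix(m[prob_cols])
  best <- max.col(probs, ties.method = "first")
  row_max <- probs[cbind(seq_len(nrow(probs)), best)]
  n_ties <- sum(rowSums(probs == row_max) > 1)
  if (n_ties > 0) {
    message(sprintf("assign_clusters: %d tie(s) broken toward the lowest cluster index",
                    n_ties))
  }
  out <- tibble::tibble(accession_id = m$accession_id, group = prob_cols[best])
  attr(out, "criterion") <- "cluster"
  class(out) <- c("cv_grouping", class(out))
  out
}

#' Choose the number of subpopulations from a cross-validation error curve
#'
#' Given CV errors for successive K values, computes the successive
#' differences `delta_K = error_{K-1} - error_K` and returns the smallest K
#' from which every subsequent difference stays below `tol` (the point where
#' the error curve plateaus). If the curve never plateaus the largest K is
#' returned with a warning.
#'
#' @param cv_errors Numeric vector of CV errors, one per K. Names are taken as
#'   K values; unnamed vectors are indexed 1..length.
#' @param tol Plateau tolerance on the error decrease.
#' @return The chosen K (integer).
#' @export
select_k_plateau <- function(cv_errors, tol) {
  if (length(cv_errors) < 3) stop("need >= 3 consecutive K values", call. = FALSE)
  ks <- if (!is.null(names(cv_errors))) as.integer(names(cv_errors)) else seq_along(cv_errors)
  delta <- -diff(cv_errors)  # error_{K-1} - error_K, indexed by the later K
  below <- delta < tol
  # smallest K whose own delta and all subsequent deltas are below tol
  ok_from <- rev(cumprod(rev(below))) == 1
  if (!any(ok_from)) {
    warning("no plateau within the K range; returning the largest K")
    return(ks[length(ks)])
  }
  ks[which(ok_from)[1] + 1L]
}

#' Build a grouping for cross-validation
#'
#' Grouping criteria mirror how a germplasm collection's records naturally
#' split: by evaluation `trial`, by `state` where the trial was grown, or by
#' genetic `cluster` of the accession (via [assign_clusters()]).
#'
#' @param ph Phenotype record tibble.
#' @param criterion `"trial"`, `"state"` or `"cluster"`.
#' @param clusters A `cv_grouping` from [assign_clusters()] (required for
#'   `criterion = "cluster"`).
#' @return A record-level tibble `accession_id`, `trial`, `group` of class
#'   `cv_grouping`.
#' @export
cv_grouping <- function(ph, criterion = c("trial", "state", "cluster"),
                        clusters = NULL) {
  criterion <- match.arg(criterion)
  ph <- validate_phenotypes(ph)
  base <- dplyr::distinct(ph, .data$accession_id, .data$trial, .data$state)
  out <- switch(criterion,
    trial = dplyr::mutate(base, group = as.character(.data$trial)),
    state = dplyr::mutate(base, group = as.character(.data$state)),
    cluster = {
      if (is.null(clusters)) stop("cluster criterion needs assign_clusters() output",
                                  call. = FALSE)
      missing_acc <- setdiff(base$accession_id, clusters$accession_id)
      if (length(missing_acc)) {
        stop("accessions without cluster assignment: ",
             paste(utils::head(missing_acc, 5), collapse = ", "), call. = FALSE)
      }
      dplyr::left_join(base, tibble::as_tibble(clusters), by = "accession_id")
    }
  )
  out <- dplyr::select(out, "accession_id", "trial", "group")
  attr(out, "criterion") <- criterion
  class(out) <- c("cv_grouping", class(out))
  out
}

#' Construct the training/validation splits of a cross-validation scheme
#'
#' The four schemes all mimic predicting accessions with no data, and all
#' enforce the leakage rule: every phenotypic record of every accession in a
#' validation set is removed from the corresponding training set.
#'
#' * `one_group`: within each group, accessions are predicted (in accession-
#'   level folds) from the remaining accessions of the same group.
#' * `one_all`: as `one_group`, but training uses records from all groups.
#' * `group_all`: each whole group is predicted from all other groups.
#' * `group_group`: each group is predicted from each single other group
#'   (ordered train -> validate pairs).
#'
#' Leave-one-accession-out is realized as accession-level k-fold splitting;
#' set `folds` at least as large as the biggest group for literal
#' leave-one-out.
#'
#' @param scheme One of `"one_group"`, `"one_all"`, `"group_all"`,
#'   `"group_group"`.
#' @param grouping A [cv_grouping()].
#' @param folds Number of accession-level folds for the leave-one-out style
#'   schemes (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return A tibble with one row per fold: `group` (validated group),
#'   `train_group` (for `group_group`), `fold`, and list-columns
#'   `val_accessions` / `train_accessions`.
#' @export
cv_folds <- function(scheme = c("one_group", "one_all", "group_all", "group_group"),
                     grouping, folds = 10, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grouping, "cv_grouping"))
  gr <- tibble::as_tibble(grouping)
  acc_groups <- gr |>
    dplyr::distinct(.data$accession_id, .data$group)
  group_ids <- sort(unique(acc_groups$group))
  all_acc <- unique(gr$accession_id)

  group_members <- split(acc_groups$accession_id, acc_groups$group)

  make_acc_folds <- function(acc, k) {
    k <- max(1L, min(k, length(acc)))
    shuffled <- sample(acc)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  }

  set.seed(seed)
  rows <- list()
  if (scheme %in% c("one_group", "one_all")) {
    for (g in group_ids) {
      members <- unique(group_members[[g]])
      fold_sets <- make_acc_folds(members, folds)
      for (f in seq_along(fold_sets)) {
        val <- fold_sets[[f]]
        train <- if (scheme == "one_group") setdiff(members, val)
                 else setdiff(all_acc, val)
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, train_group = NA_character_, fold = f,
          val_accessions = list(val), train_accessions = list(train)
        )
      }
    }
  } else if (scheme == "group_all") {
    for (g in group_ids) {
      val <- unique(group_members[[g]])
      train <- setdiff(all_acc, val)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, train_group = NA_character_, fold = 1L,
        val_accessions = list(val), train_accessions = list(train)
      )
    }
  } else {
    for (g in group_ids) {
      val <- unique(group_members[[g]])
      for (tg in setdiff(group_ids, g)) {
        train <- setdiff(unique(group_members[[tg]]), val)
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, train_group = tg, fold = 1L,
          val_accessions = list(val), train_accessions = list(train)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  overlap <- purrr::map2_int(out$train_accessions, out$val_accessions,
                             ~ length(intersect(.x, .y)))
  stopifnot("leakage: training and validation accessions overlap" = all(overlap == 0))
  attr(out, "scheme") <- scheme
  attr(out, "criterion") <- attr(grouping, "criterion")
  out
}

#' Run a cross-validation scheme
#'
#' Executes a full scheme x grouping evaluation: phenotypes are adjusted for
#' trial and maturity-group effects (fit on all records of the trait, as a
#' preprocessing of the observations), the chosen whole-genome regression is
#' refit on every training split with all records of validation accessions
#' removed, validation accessions are predicted, and predictions are
#' correlated with the accessions' adjusted phenotypes separately for each
#' group. Confidence intervals come from a paired bootstrap.
#'
#' @param scheme One of the four scheme names (see [cv_folds()]).
#' @param grouping A [cv_grouping()].
#' @param ph Phenotype record tibble.
#' @param spec A [wgr_spec()] naming the trait and model.
#' @param kinship [kinship_matrix()] covering all phenotyped accessions
#'   (required for `model = "gblup"`).
#' @param genotypes Imputed [geno_matrix()] (required for the marker models).
#' @param folds Accession-level fold count for the leave-one-out style
#'   schemes.
#' @param boot_reps Bootstrap replicates for the predictive-ability CIs.
#' @param min_val Groups with fewer validation accessions than this report
#'   `NA` predictive ability instead of failing (default 3).
#' @param seed Seed controlling fold assignment and bootstrap resampling.
#' @return A `cv_report`: tibble with `scheme`, `criterion`, `group`,
#'   `train_group`, `r`, `ci_low`, `ci_high`, `n_train`, `n_val`. The
#'   accession-level predictions are attached as attribute `"predictions"`.
#' @export
run_scheme <- function(scheme, grouping, ph, spec,
                       kinship = NULL, genotypes = NULL,
                       folds = 10, boot_reps = 10000, min_val = 3,
                       seed = 1L) {
  stopifnot(inherits(spec, "wgr_spec"))
  ph <- validate_phenotypes(ph)
  if (spec$model == "gblup" && is.null(kinship)) {
    stop("gblup needs a kinship matrix", call. = FALSE)
  }
  if (spec$model != "gblup" && is.null(genotypes)) {
    stop("marker models need a genotype matrix", call. = FALSE)
  }
  design <- fit_fixed_effects(ph, spec$trait, spec$covariates)
  adj <- adjust_phenotypes(ph, design)
  records <- adj$records

  # record-level group labels (an accession's records inherit its cluster
  # under the cluster criterion; under trial/state the record's own trial
  # decides)
  gr <- tibble::as_tibble(grouping)
  records_g <- dplyr::inner_join(records, gr, by = c("accession_id", "trial"))

  splits <- cv_folds(scheme, grouping, folds = folds, seed = seed)

  fit_one <- function(train_rec) {
    train_adj <- structure(list(
      records = train_rec,
      by_accession = train_rec |>
        dplyr::group_by(.data$accession_id) |>
        dplyr::summarise(value_adj = mean(.data$value_adj),
                         n_records = dplyr::n(), .groups = "drop"),
      trait = spec$trait, mu = design$mu
    ), class = "adjusted_phenotypes")
    switch(spec$model,
      gblup = fit_gblup(train_adj, kinship, spec),
      bayes_b = fit_bayes_b(train_adj, genotypes, spec),
      bayesian_lasso = fit_bayesian_lasso(train_adj, genotypes, spec)
    )
  }

  # observed values: adjusted phenotypes aggregated per accession *within*
  # the group being scored
  obs_by_group <- records_g |>
    dplyr::group_by(.data$group, .data$accession_id) |>
    dplyr::summarise(obs = mean(.data$value_adj), .groups = "drop")

  pred_rows <- vector("list", nrow(splits))
  for (i in seq_len(nrow(splits))) {
    val_acc <- intersect(splits$val_accessions[[i]], records$accession_id)
    # training records: within-group only for the single-group-trained
    # schemes, all groups otherwise; always purged of validation accessions
    train_rec <- switch(scheme,
      one_group = dplyr::filter(records_g, .data$group == splits$group[i]),
      group_group = dplyr::filter(records_g, .data$group == splits$train_group[i]),
      dplyr::filter(records_g, TRUE)
    )
    train_rec <- dplyr::filter(train_rec,
                               .data$accession_id %in% splits$train_accessions[[i]])
    train_acc <- unique(train_rec$accession_id)
    if (length(train_acc) < 3 || length(val_acc) == 0) next
    stopifnot(length(intersect(train_acc, val_acc)) == 0)
    fit <- fit_one(train_rec)
    preds <- if (spec$model == "gblup") {
      predict_new(fit, kinship, accessions = val_acc)
    } else {
      predict_new(fit, genotypes, accessions = val_acc)
    }
    # compile genomic values under the all-data intercept: the correlation is
    # shift-invariant within a group, but fold-specific training intercepts
    # would otherwise inject anti-correlated noise across compiled folds
    pred_rows[[i]] <- preds |>
      dplyr::transmute(.data$accession_id,
                       prediction = design$mu + (.data$prediction - fit$mu),
                       group = splits$group[i],
                       train_group = splits$train_group[i],
                       n_train_records = nrow(train_rec))
  }
  predictions <- dplyr::bind_rows(pred_rows)
  if (nrow(predictions) == 0) stop("no fold produced predictions", call. = FALSE)
  predictions <- dplyr::inner_join(predictions, obs_by_group,
                                   by = c("group", "accession_id"))

  key_cols <- if (scheme == "group_group") c("group", "train_group") else "group"
  report <- predictions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::group_modify(function(d, key) {
      n_val <- nrow(d)
      if (n_val < min_val || stats::sd(d$prediction) == 0 || stats::sd(d$obs) == 0) {
        return(tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                              n_train = round(mean(d$n_train_records)), n_val = n_val))
      }
      r <- predictive_ability(d$prediction, d$obs)
      ci <- bootstrap_ci(d$prediction, d$obs, reps = boot_reps, seed = seed)
      tibble::tibble(r = r, ci_low = ci[1], ci_high = ci[2],
                     n_train = round(mean(d$n_train_records)), n_val = n_val)
    }) |>
    dplyr::ungroup()
  if (!"train_group" %in% names(report)) report$train_group <- NA_character_
  report <- dplyr::mutate(report,
                          scheme = scheme,
                          criterion = attr(splits, "criterion"),
                          .before = 1)
  report <- dplyr::select(report, "scheme", "criterion", "group", "train_group",
                          "r", "ci_low", "ci_high", "n_train", "n_val")
  attr(report, "predictions") <- predictions
  class(report) <- c("cv_report", class(report))
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> scheme %s by %s: %d group(s), mean r = %.3f\n",
              x$scheme[1], x$criterion[1], nrow(x), mean(x$r, na.rm = TRUE)))
  NextMethod()
}

#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) tibble::as_tibble(x)

#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme[1], criterion = x$criterion[1],
    n_groups = nrow(x), n_defined = sum(!is.na(x$r)),
    mean_r = mean(x$r, na.rm = TRUE), median_r = stats::median(x$r, na.rm = TRUE),
    min_r = suppressWarnings(min(x$r, na.rm = TRUE)),
    max_r = suppressWarnings(max(x$r, na.rm = TRUE))
  )
}

#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$r))
  dat$label <- if (object$scheme[1] == "group_group") {
    paste(dat$train_group, "→", dat$group)
  } else dat$group
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$label, .data$r),
                                    y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predictive ability (Pearson r)",
                  title = sprintf("%s cross-validation by %s",
                                  object$scheme[1], object$criterion[1])) +
    ggplot2::theme_minimal()
}
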