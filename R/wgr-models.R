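#' Specify a whole-genome regression model
#'
#' Collects the model choice, MCMC settings and hyperparameters shared by
#' [fit_gblup()], [fit_bayes_b()] and [fit_bayesian_lasso()]. Hyperparameters
#' default to the variance-partition rule: a prior proportion `R2_prior` of
#' the phenotypic variance is attributed to the genomic term, prior modes of
#' the variance components are matched to that split, and for the marker
#' models the per-marker prior variance is scaled by the sum of marker
#' variances `MSx = sum(2 theta_l (1 - theta_l))`.
#'
#' @param model One of `"gblup"`, `"bayes_b"`, `"bayesian_lasso"`.
#' @param trait Trait name (used when fitting from a raw phenotype table).
#' @param covariates Fixed covariates (`"lodging"`, `"shattering"`) for the
#'   joint record-level fit.
#' @param iterations,burnin,thin MCMC settings for the Gibbs samplers.
#' @param seed Integer seed making sampler runs reproducible.
#' @param R2_prior Prior proportion of variance attributed to markers.
#' @param df_b,df_eps Prior degrees of freedom for the marker and residual
#'   variances.
#' @param pi0,p0 Bayes B beta prior on the null-marker proportion `pi`,
#'   parameterized by prior mean `pi0` and concentration `p0`
#'   (`shape1 = pi0 * p0`, `shape2 = (1 - pi0) * p0`).
#' @param pi_fixed Optional fixed value for `pi` (disables its update).
#' @param lambda_fixed Optional fixed G-BLUP shrinkage ratio
#'   `lambda = sigma2_e / sigma2_g` (skips REML).
#' @param bl_lambda2_fixed Optional fixed Bayesian LASSO regularization
#'   `lambda^2` (disables its update).
#' @param S_b,S_eps Optional explicit prior scales for the marker and
#'   residual variances, overriding the `R2_prior` rule.
#' @return A list of class `wgr_spec`.
#' @export
wgr_spec <- function(model = c("gblup", "bayes_b", "bayesian_lasso"),
                     trait = NULL, covariates = character(),
                     iterations = 12000, burnin = 2000, thin = 5,
                     seed = 1L, R2_prior = 0.5,
                     df_b = 5, df_eps = 5, pi0 = 0.5, p0 = 10,
                     pi_fixed = NULL, lambda_fixed = NULL,
                     bl_lambda2_fixed = NULL, S_b = NULL, S_eps = NULL) {
  model <- match.arg(model)
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1,
            R2_prior > 0, R2_prior < 1, p0 > 0, pi0 >= 0, pi0 <= 1)
  if (!is.null(pi_fixed)) stopifnot(pi_fixed >= 0, pi_fixed <= 1)
  structure(
    list(model = model, trait = trait, covariates = covariates,
         iterations = as.integer(iterations), burnin = as.integer(burnin),
         thin = as.integer(thin), seed = as.integer(seed),
         R2_prior = R2_prior, df_b = df_b, df_eps = df_eps,
         pi0 = pi0, p0 = p0, pi_fixed = pi_fixed,
         lambda_fixed = lambda_fixed, bl_lambda2_fixed = bl_lambda2_fixed,
         S_b = S_b, S_eps = S_eps),
    class = "wgr_spec"
  )
}

# Build the response, fixed-effect design and accession mapping for a model
# fit. Accepts either adjusted phenotypes (two-stage path: one observation per
# accession, intercept-only design) or a raw phenotype table (joint path:
# record-level observations with a (trial, MG) cell-mean design and optional
# covariates).
build_model_frame <- function(data, trait, covariates = character()) {
  if (inherits(data, "adjusted_phenotypes")) {
    ba <- data$by_accession
    F <- matrix(1, nrow(ba), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(y = ba$value_adj, F = F, acc = ba$accession_id,
                cell_trials = NULL, joint = FALSE))
  }
  ph <- validate_phenotypes(data)
  if (is.null(trait)) stop("trait must be named in the model spec", call. = FALSE)
  dat <- dplyr::filter(ph, .data$trait == !!trait)
  if (nrow(dat) == 0) stop("no records for trait ", trait, call. = FALSE)
  if (length(covariates)) {
    ok <- stats::complete.cases(dat[covariates])
    if (any(!ok)) {
      message(sprintf("dropping %d record(s) lacking covariate scores", sum(!ok)))
      dat <- dat[ok, , drop = FALSE]
    }
  }
  cell <- interaction(dat$trial, dat$maturity_group, drop = TRUE, sep = "\r")
  F <- if (nlevels(cell) == 1) {
    matrix(1, nrow(dat), 1)
  } else {
    stats::model.matrix(~ 0 + cell)
  }
  colnames(F) <- levels(cell)
  if (length(covariates)) F <- cbind(F, as.matrix(dat[covariates]))
  list(y = dat$value, F = F, acc = dat$accession_id,
       cell_trials = sub("\r.*$", "", levels(cell)), joint = TRUE)
}

# Grand mean from fitted fixed effects: intercept for the two-stage path;
# for the joint path the unweighted mean over trials of per-trial cell means
# (the same sum-to-zero convention as fit_fixed_effects).
extract_mu <- function(alpha, frame) {
  if (!frame$joint) return(unname(alpha[1]))
  cells <- alpha[seq_along(frame$cell_trials)]
  mean(tapply(cells, frame$cell_trials, mean))
}

#' Fit G-BLUP from a genomic relationship matrix
#'
#' Genetic values are modeled as `g ~ MVN(0, G sigma2_g)` with `G` the genomic
#' relationship matrix; the shrinkage ratio `lambda = sigma2_e / sigma2_g` is
#' estimated by restricted maximum likelihood, profiled over `lambda` on the
#' eigendecomposition of the record-mapped relationship matrix and maximized
#' by 1-D search. The BLUP of `g` is computed through the inversion-free form
#' `g_hat = G Z' (Z G Z' + lambda I)^{-1} (y - F alpha_hat)`, identical to the
#' textbook `[I + lambda G^{-1}]^{-1} y_adj` whenever `G` is invertible but
#' defined also for singular `G`. Accessions with several records map to a
#' single genetic value through the record-accession incidence `Z`.
#'
#' @param data An [adjust_phenotypes()] result (two-stage path) or a raw
#'   phenotype tibble (joint fit of trial/MG fixed effects and `g`).
#' @param kinship A [kinship_matrix()] whose rows cover all phenotyped
#'   accessions.
#' @param spec A [wgr_spec()] with `model = "gblup"`.
#' @return An object of class `wgr_fit`.
#' @export
fit_gblup <- function(data, kinship, spec = wgr_spec("gblup")) {
  stopifnot(inherits(kinship, "kinship_matrix"))
  frame <- build_model_frame(data, spec$trait, spec$covariates)
  missing_acc <- setdiff(unique(frame$acc), kinship$accession_ids)
  if (length(missing_acc)) {
    stop("accessions absent from kinship matrix: ",
         paste(utils::head(missing_acc, 5), collapse = ", "), call. = FALSE)
  }
  y <- frame$y; F <- frame$F
  N <- length(y); q <- ncol(F)
  tr_ids <- unique(frame$acc)
  idx <- match(frame$acc, tr_ids)
  G_tr <- kinship$G[tr_ids, tr_ids, drop = FALSE]
  H <- G_tr[idx, idx, drop = FALSE]  # Z G Z'

  eg <- eigen(H, symmetric = TRUE)
  U <- eg$vectors
  D <- pmax(eg$values, 0)
  ys <- drop(crossprod(U, y))
  Fs <- crossprod(U, F)

  reml_pieces <- function(lambda) {
    d <- D + lambda
    A <- crossprod(Fs, Fs / d)
    beta <- solve(A, crossprod(Fs, ys / d))
    r <- ys - Fs %*% beta
    s2g <- sum(r^2 / d) / (N - q)
    ll <- -0.5 * ((N - q) * log(s2g) + sum(log(d)) +
                    determinant(A, logarithm = TRUE)$modulus + (N - q))
    list(ll = as.numeric(ll), beta = drop(beta), s2g = s2g, d = d, r = drop(r))
  }

  if (is.null(spec$lambda_fixed)) {
    opt <- stats::optimize(function(lv) reml_pieces(exp(lv))$ll,
                           interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
    lambda <- exp(opt$maximum)
  } else {
    lambda <- spec$lambda_fixed
  }
  pieces <- reml_pieces(lambda)
  alpha <- stats::setNames(pieces$beta, colnames(F))
  sigma2_g <- pieces$s2g
  sigma2_e <- lambda * sigma2_g

  # t = (H + lambda I)^{-1} residual, then fold records onto accessions
  t_vec <- drop(U %*% (pieces$r / pieces$d))
  v <- drop(rowsum(t_vec, idx))         # Z' t, ordered by accession index
  v <- stats::setNames(v[order(unique(idx))], tr_ids)
  v <- v[tr_ids]
  g_hat <- drop(G_tr %*% v)
  names(g_hat) <- tr_ids

  new_wgr_fit(
    model = "gblup", trait = spec$trait, frame = frame,
    mu = extract_mu(alpha, frame), alpha = alpha,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, lambda = lambda,
    g_hat = g_hat, v = v, spec = spec,
    extras = list(reml_loglik = pieces$ll, g_diag_mean = mean(diag(G_tr)))
  )
}

# shared scaffolding for sampler-based marker fits
marker_fit_inputs <- function(data, genotypes, spec) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (anyNA(genotypes$dosages)) {
    stop("genotypes contain missing calls; impute_missing() first", call. = FALSE)
  }
  frame <- build_model_frame(data, spec$trait, spec$covariates)
  missing_acc <- setdiff(unique(frame$acc), genotypes$accession_ids)
  if (length(missing_acc)) {
    stop("accessions absent from genotype matrix: ",
         paste(utils::head(missing_acc, 5), collapse = ", "), call. = FALSE)
  }
  theta <- genotypes$theta
  Xc_acc <- sweep(genotypes$dosages, 2, 2 * theta, "-")
  tr_ids <- unique(frame$acc)
  X <- Xc_acc[match(frame$acc, rownames(Xc_acc)), , drop = FALSE]
  msx <- sum(2 * theta * (1 - theta))
  list(frame = frame, X = X, Xc_acc = Xc_acc, tr_ids = tr_ids,
       theta = theta, msx = msx, vy = stats::var(frame$y))
}

#' Fit the Bayes B mixture model
#'
#' Marker effects follow the spike-and-slab mixture `p(b_l) = pi * delta_0 +
#' (1 - pi) * N(0, sigma2_bl)` with per-marker variances given scaled inverse
#' chi-squared priors and a beta prior on the null proportion `pi`. A Gibbs
#' sampler cycles over fixed effects, per-marker inclusion indicators and
#' effects (with the indicator drawn from its marginal odds), marker
#' variances, `pi` and the residual variance. Posterior means of the marker
#' effects, per-marker posterior inclusion probabilities and genetic values
#' `g_i = sum_l (x_il - 2 theta_l) b_l` are reported.
#'
#' @inheritParams fit_gblup
#' @param genotypes An imputed [geno_matrix()] for at least the phenotyped
#'   accessions.
#' @return A `wgr_fit` with elements `b`, `pip` and `pi`.
#' @export
fit_bayes_b <- function(data, genotypes, spec = wgr_spec("bayes_b")) {
  inp <- marker_fit_inputs(data, genotypes, spec)
  R2 <- spec$R2_prior
  S_eps <- spec$S_eps %||% (inp$vy * (1 - R2) * (spec$df_eps + 2))
  pi_eff <- if (is.null(spec$pi_fixed)) spec$pi0 else spec$pi_fixed
  S_b <- spec$S_b %||%
    (inp$vy * R2 * (spec$df_b + 2) / (max(1 - pi_eff, 0.01) * inp$msx))

  set.seed(spec$seed)
  res <- .bayes_b_gibbs(inp$frame$y, inp$X, inp$frame$F,
                        spec$iterations, spec$burnin, spec$thin,
                        spec$df_b, S_b, spec$pi0, spec$p0,
                        spec$df_eps, S_eps,
                        !is.null(spec$pi_fixed),
                        if (is.null(spec$pi_fixed)) 0 else spec$pi_fixed)
  b <- stats::setNames(drop(res$b), colnames(inp$X))
  g_hat <- drop(inp$Xc_acc[inp$tr_ids, , drop = FALSE] %*% b)
  alpha <- stats::setNames(drop(res$alpha), colnames(inp$frame$F))
  new_wgr_fit(
    model = "bayes_b", trait = spec$trait, frame = inp$frame,
    mu = extract_mu(alpha, inp$frame), alpha = alpha,
    sigma2_g = stats::var(g_hat), sigma2_e = res$sigma2_e, lambda = NA_real_,
    g_hat = stats::setNames(g_hat, inp$tr_ids), v = NULL, spec = spec,
    b = b, theta = inp$theta, marker_ids = colnames(inp$X),
    extras = list(pip = stats::setNames(drop(res$pip), colnames(inp$X)),
                  pi = res$pi, sigma2_e_sd = res$sigma2_e_sd,
                  n_saved = res$n_saved)
  )
}

#' Fit the Bayesian LASSO
#'
#' Marker effects have conditionally normal priors `b_l ~ N(0, tau2_l
#' sigma2_e)` with iid exponential prior variances, so the marginal prior is
#' double exponential and shrinkage is adaptive. The Gibbs sampler follows the
#' standard augmentation: inverse-Gaussian updates for `1/tau2_l`, a gamma
#' update for the regularization parameter `lambda^2`, and a scaled inverse
#' chi-squared update for the residual variance. The prior mode of `lambda^2`
#' is set so the implied marker variance matches the `R2_prior` split of
#' phenotypic variance, `lambda^2 = 2 MSx (1 - R2) / R2`.
#'
#' @inheritParams fit_bayes_b
#' @return A `wgr_fit` with elements `b` and `lambda2`.
#' @export
fit_bayesian_lasso <- function(data, genotypes, spec = wgr_spec("bayesian_lasso")) {
  inp <- marker_fit_inputs(data, genotypes, spec)
  R2 <- spec$R2_prior
  S_eps <- spec$S_eps %||% (inp$vy * (1 - R2) * (spec$df_eps + 2))
  lambda2_mode <- 2 * inp$msx * (1 - R2) / R2
  lambda_shape <- 1.1
  lambda_rate <- (lambda_shape - 1) / lambda2_mode
  fixed <- !is.null(spec$bl_lambda2_fixed)
  lambda2_init <- if (fixed) spec$bl_lambda2_fixed else lambda2_mode

  set.seed(spec$seed)
  res <- .bayes_lasso_gibbs(inp$frame$y, inp$X, inp$frame$F,
                            spec$iterations, spec$burnin, spec$thin,
                            lambda2_init, lambda_shape, lambda_rate, fixed,
                            spec$df_eps, S_eps)
  b <- stats::setNames(drop(res$b), colnames(inp$X))
  g_hat <- drop(inp$Xc_acc[inp$tr_ids, , drop = FALSE] %*% b)
  alpha <- stats::setNames(drop(res$alpha), colnames(inp$frame$F))
  new_wgr_fit(
    model = "bayesian_lasso", trait = spec$trait, frame = inp$frame,
    mu = extract_mu(alpha, inp$frame), alpha = alpha,
    sigma2_g = stats::var(g_hat), sigma2_e = res$sigma2_e, lambda = NA_real_,
    g_hat = stats::setNames(g_hat, inp$tr_ids), v = NULL, spec = spec,
    b = b, theta = inp$theta, marker_ids = colnames(inp$X),
    extras = list(lambda2 = res$lambda2, sigma2_e_sd = res$sigma2_e_sd,
                  n_saved = res$n_saved)
  )
}

new_wgr_fit <- function(model, trait, frame, mu, alpha, sigma2_g, sigma2_e,
                        lambda, g_hat, v, spec, b = NULL, theta = NULL,
                        marker_ids = NULL, extras = list()) {
  structure(
    c(list(model = model, trait = trait, mu = mu, alpha = alpha,
           sigma2_g = sigma2_g, sigma2_e = sigma2_e, lambda = lambda,
           g_hat = g_hat, v = v, b = b, theta = theta,
           marker_ids = marker_ids,
           phenotyped_ids = names(g_hat),
           n_obs = length(frame$y), spec = spec),
      extras),
    class = "wgr_fit"
  )
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf(
    "<wgr_fit> %s on trait %s: %d obs, %d accessions\n  mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g%s\n",
    x$model, x$trait %||% "?", x$n_obs, length(x$g_hat), x$mu, x$sigma2_g,
    x$sigma2_e,
    if (x$model == "gblup") sprintf(", lambda = %.4g", x$lambda) else ""
  ))
  invisible(x)
}

#' Predict genetic merit of new accessions
#'
#' For marker-effect models (`bayes_b`, `bayesian_lasso`) the prediction for
#' accession `i` is `mu + sum_l (x_il - 2 theta_l) b_l`, using the training
#' allele frequencies for centering; an accession whose dosages all sit at the
#' training mean therefore predicts exactly `mu`. For G-BLUP, supply the joint
#' kinship of training and new accessions: the new genetic values are
#' `G_no (G_oo + lambda I)^{-1} y_resid` and predictions are reported with the
#' intercept added, on the trait measurement scale.
#'
#' @param fit A `wgr_fit`.
#' @param newdata A [geno_matrix()] for marker models, or a joint
#'   [kinship_matrix()] (training + new accessions) for G-BLUP.
#' @param accessions Which accessions to predict; defaults to all accessions
#'   in `newdata` not used in training.
#' @return A tibble with `accession_id`, `prediction` and `phenotyped`.
#' @export
predict_new <- function(fit, newdata, accessions = NULL) {
  stopifnot(inherits(fit, "wgr_fit"))
  if (fit$model == "gblup") {
    stopifnot(inherits(newdata, "kinship_matrix"))
    tr <- names(fit$v)
    missing_tr <- setdiff(tr, newdata$accession_ids)
    if (length(missing_tr)) {
      stop("joint kinship lacks training accessions: ",
           paste(utils::head(missing_tr, 5), collapse = ", "), call. = FALSE)
    }
    if (is.null(accessions)) accessions <- setdiff(newdata$accession_ids, tr)
    g_new <- drop(newdata$G[accessions, tr, drop = FALSE] %*% fit$v)
  } else {
    stopifnot(inherits(newdata, "geno_matrix"))
    missing_m <- setdiff(fit$marker_ids, newdata$marker_ids)
    if (length(missing_m)) {
      stop("new genotypes lack training markers: ",
           paste(utils::head(missing_m, 5), collapse = ", "),
           sprintf(" (%d total)", length(missing_m)), call. = FALSE)
    }
    if (is.null(accessions)) accessions <- newdata$accession_ids
    X <- newdata$dosages[accessions, fit$marker_ids, drop = FALSE]
    if (anyNA(X)) stop("new genotypes contain missing calls; impute first",
                       call. = FALSE)
    Xc <- sweep(X, 2, 2 * fit$theta, "-")
    g_new <- drop(Xc %*% fit$b)
  }
  tibble::tibble(
    accession_id = accessions,
    prediction = fit$mu + unname(g_new),
    phenotyped = accessions %in% fit$phenotyped_ids
  )
}

#' Tidy marker or accession-level results of a whole-genome regression
#'
#' @param x A `wgr_fit`.
#' @param effects `"accessions"` (genetic values) or `"markers"` (marker
#'   effects, with posterior inclusion probabilities for Bayes B).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wgr_fit
#' @export
tidy.wgr_fit <- function(x, effects = c("accessions", "markers"), ...) {
  effects <- match.arg(effects)
  if (effects == "accessions") {
    return(tibble::tibble(accession_id = names(x$g_hat),
                          g_hat = unname(x$g_hat),
                          prediction = x$mu + unname(x$g_hat)))
  }
  if (is.null(x$b)) stop("G-BLUP fits carry no per-marker effects", call. = FALSE)
  out <- tibble::tibble(marker_id = names(x$b), estimate = unname(x$b))
  if (!is.null(x$pip)) out$pip <- unname(x$pip)
  out
}

#' One-row summary of a whole-genome regression fit
#'
#' @param x A `wgr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the variance components, shrinkage ratio and
#'   implied genomic heritability. For G-BLUP the genetic variance is scaled
#'   by the mean diagonal of the training relationship matrix (about 2 for a
#'   fully inbred panel), since the genomic variance of accession `i` is
#'   `sigma2_g * G_ii`; for the marker models `sigma2_g` is already the
#'   variance of the fitted genetic values.
#' @method glance wgr_fit
#' @export
glance.wgr_fit <- function(x, ...) {
  vg <- x$sigma2_g * (x$g_diag_mean %||% 1)
  tibble::tibble(
    model = x$model, trait = x$trait %||% NA_character_,
    n_obs = x$n_obs, n_accessions = length(x$g_hat),
    mu = x$mu, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
    lambda = x$lambda,
    h2_genomic = vg / (vg + x$sigma2_e)
  )
}

#' @method autoplot wgr_fit
#' @export
autoplot.wgr_fit <- function(object, ...) {
  dat <- tidy.wgr_fit(object, "accessions")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$g_hat)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(
      x = "estimated genetic value",
      y = "accessions",
      title = sprintf("%s genetic values (%s)", object$model,
                      object$trait %||% "trait")
    ) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
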