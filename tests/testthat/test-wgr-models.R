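# helper: accession-level adjusted phenotypes from a plain named vector
as_adjusted <- function(y, trait = "oil") {
  structure(list(
    records = NULL,
    by_accession = tibble::tibble(accession_id = names(y), value_adj = unname(y),
                                  n_records = 1L),
    trait = trait, mu = mean(y)
  ), class = "adjusted_phenotypes")
}

test_that("identity kinship with lambda = 1 halves centered phenotypes", {
  set.seed(10)
  n <- 12
  ids <- sprintf("a%02d", 1:n)
  y <- rnorm(n); y <- y - mean(y)
  K <- kinship_matrix(diag(n) |> `dimnames<-`(list(ids, ids)))
  fit <- fit_gblup(as_adjusted(setNames(y, ids)), K,
                   wgr_spec("gblup", lambda_fixed = 1))
  expect_equal(unname(fit$g_hat[ids]), y / 2, tolerance = 1e-8)
})

test_that("the inversion-free BLUP equals the explicit-inverse formula", {
  dos <- random_inbred_panel(8, 60, seed = 21)
  g <- geno_matrix(dos)
  K <- compute_grm(g)
  # make G invertible by a ridge so the printed [I + lambda G^-1]^-1 form exists
  G <- K$G + diag(0.05, 8)
  dimnames(G) <- dimnames(K$G)
  Kr <- kinship_matrix(G)
  set.seed(22)
  y <- setNames(rnorm(8), rownames(dos))
  lambda <- 0.5
  fit <- fit_gblup(as_adjusted(y), Kr, wgr_spec("gblup", lambda_fixed = lambda))
  yc <- y - fit$alpha[1]
  g_direct <- solve(diag(8) + lambda * solve(G)) %*% yc
  expect_equal(unname(fit$g_hat[names(y)]), unname(drop(g_direct)),
               tolerance = 1e-8)
})

test_that("infinite shrinkage collapses genetic values to zero", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  fit <- fit_gblup(adj, pan$K, wgr_spec("gblup", trait = "oil", lambda_fixed = 1e8))
  expect_lt(max(abs(fit$g_hat)), 1e-4)
})

test_that("G-BLUP predictions equal ridge marker regression with matched penalty", {
  for (seed in c(31, 32, 33)) {
    n <- 30; p <- 100
    dos <- random_inbred_panel(n + 5, p, seed = seed)
    g <- geno_matrix(dos)
    W <- standardized_scores(g)
    tr <- rownames(dos)[1:n]; new <- rownames(dos)[(n + 1):(n + 5)]
    set.seed(seed)
    y <- setNames(rnorm(n), tr)
    K <- compute_grm(g)
    lambda <- 0.7
    fit <- fit_gblup(as_adjusted(y), kinship_matrix(K$G[tr, tr]),
                     wgr_spec("gblup", lambda_fixed = lambda))
    orc <- ridge_oracle_predict(W[tr, ], y, lambda, W[new, ])
    expect_equal(unname(fit$mu + fit$g_hat[tr]), orc$fitted, tolerance = 1e-8)
    pred <- predict_new(fit, K, accessions = new)
    expect_equal(pred$prediction, orc$pred, tolerance = 1e-8)
  }
})

test_that("REML recovers heritability and ranks accessions on synthetic data", {
  cfg <- sim_config(n_accessions = 500, p_markers = 1000, n_trials = 8, seed = 77)
  col <- simulate_collection(cfg)
  gi <- impute_missing(filter_markers(col$genotypes)$genotypes)
  K <- compute_grm(gi)
  d <- fit_fixed_effects(col$phenotypes, "oil")
  adj <- adjust_phenotypes(col$phenotypes, d)
  fit <- fit_gblup(adj, K, wgr_spec("gblup", trait = "oil"))
  h2_hat <- fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  # oil is simulated at record-level h2 = 0.6; the accession-level REML
  # estimate is attenuated by G x E but must sit in a sane band
  expect_gt(h2_hat, 0.3)
  expect_lt(h2_hat, 0.85)
  truth <- col$truth$genetic_values$oil[names(fit$g_hat)]
  expect_gt(cor(fit$g_hat, truth), 0.6)
})

test_that("phenotype shifts move only the intercept", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  fit1 <- fit_gblup(adj, pan$K, wgr_spec("gblup", trait = "oil"))
  adj2 <- adj
  adj2$by_accession$value_adj <- adj2$by_accession$value_adj + 5
  fit2 <- fit_gblup(adj2, pan$K, wgr_spec("gblup", trait = "oil"))
  expect_equal(fit2$mu, fit1$mu + 5, tolerance = 1e-6)
  expect_equal(fit2$g_hat, fit1$g_hat, tolerance = 1e-6)
})

test_that("samplers are bit-reproducible under a fixed seed", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  sp <- wgr_spec("bayes_b", trait = "oil", iterations = 400, burnin = 100,
                 thin = 2, seed = 99)
  f1 <- fit_bayes_b(adj, pan$geno, sp)
  f2 <- fit_bayes_b(adj, pan$geno, sp)
  expect_identical(f1$b, f2$b)
  expect_identical(f1$g_hat, f2$g_hat)
  sp2 <- wgr_spec("bayesian_lasso", trait = "oil", iterations = 400,
                  burnin = 100, thin = 2, seed = 99)
  expect_identical(fit_bayesian_lasso(adj, pan$geno, sp2)$b,
                   fit_bayesian_lasso(adj, pan$geno, sp2)$b)
})

test_that("pure-noise responses are shrunk far below single-marker OLS", {
  set.seed(41)
  n <- 200; p <- 500
  dos <- random_inbred_panel(n, p, seed = 41)
  g <- geno_matrix(dos)
  y <- setNames(rnorm(n), rownames(dos))
  adj <- as_adjusted(y)
  sp <- wgr_spec("bayesian_lasso", iterations = 1500, burnin = 500, seed = 5)
  fit <- fit_bayesian_lasso(adj, g, sp)
  Xc <- sweep(dos, 2, 2 * g$theta, "-")
  ols_max <- max(abs(crossprod(Xc, y - mean(y)) / colSums(Xc^2)))
  expect_lt(max(abs(fit$b)), 0.10 * ols_max)

  # residual-variance calibration: posterior mean covers the truth
  expect_lt(abs(fit$sigma2_e - 1), 2 * max(fit$sigma2_e_sd, 0.05) + 0.15)
})

test_that("the conjugate single-variance subcase matches the closed form", {
  # pin the marker and residual variances through extreme prior df so the
  # sampler reduces to a normal-normal model with known posterior mean
  set.seed(51)
  n <- 80
  x <- sample(c(0, 2), n, replace = TRUE)
  ids <- sprintf("a%02d", 1:n)
  dos <- cbind(m1 = x); rownames(dos) <- ids
  g <- geno_matrix(dos)
  b_true <- 0.4
  y <- setNames(x * b_true + rnorm(n, 0, 1), ids)
  v_b <- 0.25; v_e <- 1.0
  df_pin <- 1e8
  sp <- wgr_spec("bayes_b", iterations = 6000, burnin = 1000, thin = 1,
                 seed = 13, pi_fixed = 0, df_b = df_pin, df_eps = df_pin,
                 S_b = v_b * df_pin, S_eps = v_e * df_pin)
  fit <- fit_bayes_b(as_adjusted(y), g, sp)
  xc <- x - mean(x)
  yc <- y - mean(y)
  b_closed <- sum(xc * yc) / (sum(xc^2) + v_e / v_b)
  expect_equal(unname(fit$b), b_closed, tolerance = 0.03)
})

test_that("Bayes B with pi fixed at 1 predicts the fixed-effect mean", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  sp <- wgr_spec("bayes_b", trait = "oil", iterations = 600, burnin = 200,
                 seed = 3, pi_fixed = 1)
  fit <- fit_bayes_b(adj, pan$geno, sp)
  expect_equal(max(abs(fit$g_hat)), 0)
  pred <- predict_new(fit, pan$geno, accessions = pan$geno$accession_ids[1:5])
  expect_equal(pred$prediction, rep(fit$mu, 5), tolerance = 1e-10)
})

test_that("Bayes B assigns higher inclusion to true QTL than to null markers", {
  cfg <- sim_config(n_accessions = 300, p_markers = 600, n_trials = 5,
                    architecture = "sparse", n_qtl = 20, seed = 61)
  col <- simulate_collection(cfg)
  gi <- impute_missing(filter_markers(col$genotypes)$genotypes)
  d <- fit_fixed_effects(col$phenotypes, "oil")
  adj <- adjust_phenotypes(col$phenotypes, d)
  sp <- wgr_spec("bayes_b", trait = "oil", iterations = 2000, burnin = 500,
                 seed = 8, pi0 = 0.9, p0 = 20)
  fit <- fit_bayes_b(adj, gi, sp)
  qtl <- names(which(col$truth$marker_effects$oil != 0))
  qtl <- intersect(qtl, names(fit$pip))
  expect_gt(mean(fit$pip[qtl]), mean(fit$pip[setdiff(names(fit$pip), qtl)]))
})

test_that("duplicating every marker leaves Bayesian LASSO predictions stable", {
  set.seed(71)
  n <- 120; p <- 80
  dos <- random_inbred_panel(n, p, seed = 71)
  g1 <- geno_matrix(dos)
  W <- standardized_scores(g1)
  b <- rnorm(p, 0, 0.15)
  y <- setNames(drop(W %*% b) + rnorm(n, 0, 0.5), rownames(dos))
  adj <- as_adjusted(y)
  dup <- cbind(dos, dos)
  colnames(dup) <- c(colnames(dos), paste0(colnames(dos), "_dup"))
  g2 <- geno_matrix(dup)
  sp <- wgr_spec("bayesian_lasso", iterations = 3000, burnin = 1000, seed = 17)
  f1 <- fit_bayesian_lasso(adj, g1, sp)
  f2 <- fit_bayesian_lasso(adj, g2, sp)
  expect_gt(cor(f1$g_hat[names(y)], f2$g_hat[names(y)]), 0.98)
  expect_lt(mean(abs(f1$g_hat[names(y)] - f2$g_hat[names(y)])), 0.1 * sd(y))
})

test_that("marker predictions center at mu for mean dosages and match training", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  sp <- wgr_spec("bayes_b", trait = "oil", iterations = 800, burnin = 200, seed = 7)
  fit <- fit_bayes_b(adj, pan$geno, sp)

  # an accession whose dosages equal 2 theta everywhere predicts exactly mu
  mean_dos <- matrix(2 * pan$geno$theta, 1,
                     dimnames = list("meanacc", pan$geno$marker_ids))
  gm <- geno_matrix(rbind(pan$geno$dosages, mean_dos), theta = pan$geno$theta,
                    validate = FALSE)
  pred <- predict_new(fit, gm, accessions = "meanacc")
  expect_equal(pred$prediction, fit$mu, tolerance = 1e-10)

  # a clone of a training accession reproduces its fitted value exactly
  clone_of <- pan$geno$accession_ids[1]
  pred2 <- predict_new(fit, pan$geno, accessions = clone_of)
  expect_equal(pred2$prediction, unname(fit$mu + fit$g_hat[clone_of]),
               tolerance = 1e-10)

  # marker mismatch is refused
  g_bad <- geno_matrix(pan$geno$dosages[, 1:10])
  expect_error(predict_new(fit, g_bad), "lack training markers")
})

test_that("tidy and glance expose fit summaries", {
  pan <- small_panel()
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  fit <- fit_gblup(adj, pan$K, wgr_spec("gblup", trait = "oil"))
  td <- tidy(fit)
  expect_true(all(c("accession_id", "g_hat", "prediction") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$lambda, fit$sigma2_e / fit$sigma2_g, tolerance = 1e-8)
  expect_error(tidy(fit, "markers"), "no per-marker")
})
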