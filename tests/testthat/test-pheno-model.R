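test_that("single-cell designs reduce to the trait mean", {
  set.seed(1)
  ph <- make_records(sprintf("a%d", 1:20), "T1", "S1", 2, rnorm(20, 5))
  d <- fit_fixed_effects(ph, "oil")
  expect_equal(d$mu, mean(ph$value), tolerance = 1e-10)
  expect_equal(d$trial_effects$effect, 0, tolerance = 1e-10)
  expect_equal(d$mg_effects$effect, 0, tolerance = 1e-10)
})

test_that("constructed trial offsets are recovered as effect contrasts", {
  set.seed(2)
  base <- rnorm(30)
  ph <- dplyr::bind_rows(
    make_records(sprintf("a%d", 1:30), "T1", "S1", 3, base + 1),
    make_records(sprintf("a%d", 1:30), "T2", "S2", 3, base - 1)
  )
  d <- fit_fixed_effects(ph, "oil")
  eff <- tibble::deframe(d$trial_effects)
  expect_equal(unname(eff["T1"] - eff["T2"]), 2, tolerance = 1e-8)
})

test_that("generator trial and MG effects are recovered from synthetic records", {
  col <- small_collection()
  d <- fit_fixed_effects(col$phenotypes, "oil")
  units <- col$truth$trait_units
  sc <- units$scale[units$trait == "oil"]
  est <- tibble::deframe(d$trial_effects)
  truth <- col$truth$trial_effects[names(est)] * sc
  # strong agreement up to estimation noise in modest cells
  expect_gt(cor(est, truth), 0.9)
  expect_lt(mean(abs(est - (truth - mean(truth)))), 3 * sd(truth) / sqrt(length(truth)) + 0.2)
})

test_that("adjustment removes fitted effects and respects cell structure", {
  col <- small_collection()
  d <- fit_fixed_effects(col$phenotypes, "oil")
  adj <- adjust_phenotypes(col$phenotypes, d)
  # within every (trial, MG) cell the adjusted records center at mu
  cell_means <- adj$records |>
    dplyr::group_by(.data$trial, .data$maturity_group) |>
    dplyr::summarise(m = mean(.data$value_adj), .groups = "drop")
  expect_lt(max(abs(cell_means$m - d$mu)), 1e-8)

  # refitting on the adjusted values leaves no fixed effects behind
  ph2 <- dplyr::mutate(adj$records, value = .data$value_adj)
  d2 <- fit_fixed_effects(ph2, "oil")
  expect_lt(max(abs(d2$trial_effects$effect)), 1e-8)
  expect_lt(max(abs(d2$mg_effects$effect)), 1e-8)

  # identity when the design has no effects to remove
  d0 <- d
  d0$cell_fit$fit <- d0$mu
  adj0 <- adjust_phenotypes(col$phenotypes, d0)
  oil <- dplyr::filter(col$phenotypes, trait == "oil")
  expect_equal(adj0$records$value_adj, oil$value, tolerance = 1e-12)
})

test_that("record-level examples follow the definition of the adjustment", {
  ph <- dplyr::bind_rows(
    make_records(c("a1", "a2", "a3"), "T1", "S1", 1, c(3.0, 2.0, 2.5)),
    make_records(c("a1", "a4", "a5"), "T2", "S1", 1, c(4.0, 3.0, 3.5))
  )
  d <- fit_fixed_effects(ph, "oil")
  adj <- adjust_phenotypes(ph, d)
  # a record equals cell fit => adjusted value equals mu
  rec <- dplyr::filter(adj$records, .data$accession_id == "a2")
  cell_fit_t1 <- d$cell_fit$fit[d$cell_fit$trial == "T1"]
  expect_equal(rec$value_adj, 2.0 - cell_fit_t1 + d$mu, tolerance = 1e-10)
  # accession in two trials -> aggregate is the mean of its adjusted records
  a1 <- dplyr::filter(adj$records, .data$accession_id == "a1")
  agg <- dplyr::filter(adj$by_accession, .data$accession_id == "a1")
  expect_equal(agg$value_adj, mean(a1$value_adj), tolerance = 1e-12)
  expect_equal(agg$n_records, 2L)

  unseen <- make_records("a9", "T9", "S9", 1, 1.0)
  expect_error(adjust_phenotypes(dplyr::bind_rows(ph, unseen), d), "unseen")
})

test_that("shifting all records moves only the grand mean", {
  col <- small_collection()
  ph <- dplyr::filter(col$phenotypes, trait == "oil")
  d1 <- fit_fixed_effects(ph, "oil")
  a1 <- adjust_phenotypes(ph, d1)
  ph2 <- dplyr::mutate(ph, value = value + 7)
  d2 <- fit_fixed_effects(ph2, "oil")
  a2 <- adjust_phenotypes(ph2, d2)
  expect_equal(d2$mu, d1$mu + 7, tolerance = 1e-8)
  expect_equal(a2$by_accession$value_adj - d2$mu,
               a1$by_accession$value_adj - d1$mu, tolerance = 1e-8)
})

test_that("lodging/shattering covariates are estimated and removed", {
  set.seed(4)
  n <- 200
  lodging <- sample(1:5, n, replace = TRUE)
  y <- 10 + rnorm(n, 0, 0.3) - 0.5 * (lodging - 1)
  ph <- make_records(sprintf("a%d", 1:n), "T1", "S1", 2, y, trait = "yield",
                     lodging = lodging, shattering = sample(1:5, n, TRUE))
  d <- fit_fixed_effects(ph, "yield", covariates = "lodging")
  expect_equal(unname(d$covariate_coefs["lodging"]), -0.5, tolerance = 0.05)
  adj <- adjust_phenotypes(ph, d)
  expect_lt(abs(cor(adj$records$value_adj, lodging)), 0.15)
})

test_that("entry-mean heritability matches its closed form and limits", {
  # zero residual noise -> H2 = 1
  ph <- tidyr::expand_grid(accession_id = sprintf("a%d", 1:30), rep = 1:3)
  ph$value <- rep(rnorm(30, 0, 2), each = 3) + 0.1 * ph$rep
  expect_equal(as.numeric(entry_mean_heritability(ph)), 1, tolerance = 1e-6)

  # zero accession variance -> H2 = 0
  set.seed(6)
  ph0 <- tidyr::expand_grid(accession_id = sprintf("a%d", 1:40), rep = 1:4)
  ph0$value <- rnorm(nrow(ph0))
  expect_lt(as.numeric(entry_mean_heritability(ph0)), 0.25)

  expect_error(
    entry_mean_heritability(dplyr::filter(ph, rep == 1)),
    "heritability undefined"
  )

  # sigma2_A = 3 sigma2_eps with 4 reps -> H2 = 12/13
  set.seed(7)
  h2s <- replicate(40, {
    g <- rnorm(200, 0, sqrt(3))
    d <- tidyr::expand_grid(accession_id = sprintf("a%03d", 1:200), rep = 1:4)
    d$value <- g[as.integer(factor(d$accession_id))] + rnorm(nrow(d)) +
      c(0, 0.5, -0.2, 0.1)[d$rep]
    as.numeric(entry_mean_heritability(d))
  })
  expect_lt(abs(mean(h2s) - 12 / 13), 0.03)
})

test_that("heritability is invariant to affine rescaling of the trait", {
  set.seed(8)
  g <- rnorm(100, 0, 1.5)
  d <- tidyr::expand_grid(accession_id = sprintf("a%03d", 1:100), rep = 1:3)
  d$value <- g[as.integer(factor(d$accession_id))] + rnorm(nrow(d))
  h1 <- as.numeric(entry_mean_heritability(d))
  d2 <- dplyr::mutate(d, value = 3.7 * value + 11)
  expect_equal(as.numeric(entry_mean_heritability(d2)), h1, tolerance = 1e-6)
})
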