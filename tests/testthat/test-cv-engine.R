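test_that("cluster assignment is argmax with ties to the lowest index", {
  m <- tibble::tibble(accession_id = c("a1", "a2"),
                      cluster1 = c(0.7, 0.5), cluster2 = c(0.2, 0.5),
                      cluster3 = c(0.1, 0.0))
  expect_message(g <- assign_clusters(m), "1 tie")
  expect_identical(g$group, c("cluster1", "cluster1"))

  bad <- tibble::tibble(accession_id = "x", cluster1 = 0.7, cluster2 = 0.2)
  expect_error(assign_clusters(bad), "sum to 1")
})

test_that("cluster assignment equals a brute-force row-by-row argmax", {
  col <- small_collection()
  g <- assign_clusters(col$membership)
  probs <- as.matrix(col$membership[setdiff(names(col$membership), "accession_id")])
  manual <- character(nrow(probs))
  for (i in seq_len(nrow(probs))) {
    manual[i] <- colnames(probs)[which.max(probs[i, ])]
  }
  expect_identical(g$group, manual)
})

test_that("the plateau rule picks the first K where improvements stay small", {
  expect_equal(select_k_plateau(c(10, 6, 5.9, 5.85), tol = 0.2), 3)
  expect_warning(k <- select_k_plateau(c(10, 8, 6, 4), tol = 0), "no plateau")
  expect_equal(k, 4)
  expect_error(select_k_plateau(c(1, 2), tol = 1), ">= 3")

  # random error sequences match a brute-force scan
  set.seed(123)
  for (rep in 1:20) {
    errs <- cumsum(rnorm(10, -0.5, 1)) + 20
    tol <- runif(1, 0, 1)
    deltas <- -diff(errs)
    brute <- NA
    for (k in 2:10) {
      if (all(deltas[(k - 1):9] < tol)) { brute <- k; break }
    }
    if (is.na(brute)) {
      expect_warning(got <- select_k_plateau(errs, tol))
      expect_equal(got, 10)
    } else {
      expect_equal(select_k_plateau(errs, tol), brute)
    }
  }
})

test_that("group-by-group folds enumerate ordered pairs", {
  ph <- dplyr::bind_rows(
    make_records(sprintf("a%d", 1:6), "T1", "S1", 1, rnorm(6)),
    make_records(sprintf("b%d", 1:6), "T2", "S1", 1, rnorm(6))
  )
  gr <- cv_grouping(ph, "trial")
  f <- cv_folds("group_group", gr)
  expect_equal(nrow(f), 2)
  expect_setequal(paste(f$train_group, f$group), c("T1 T2", "T2 T1"))
})

test_that("no fold of any scheme leaks a validation accession into training", {
  col <- small_collection()
  clusters <- assign_clusters(col$membership)
  for (crit in c("trial", "state", "cluster")) {
    gr <- cv_grouping(col$phenotypes, crit,
                      clusters = if (crit == "cluster") clusters else NULL)
    for (sch in c("one_group", "one_all", "group_all", "group_group")) {
      f <- cv_folds(sch, gr, folds = 5, seed = 2)
      overlap <- purrr::map2_int(f$train_accessions, f$val_accessions,
                                 ~ length(intersect(.x, .y)))
      expect_equal(max(overlap), 0L)
      # within a scheme the validation sets cover the grouping's accessions
      expect_setequal(unique(unlist(f$val_accessions)),
                      unique(tibble::as_tibble(gr)$accession_id))
    }
  }
})

test_that("an accession spanning two trials is fully purged from training", {
  # a1 has records in T1 and T2; when a1 is validated (whatever the group),
  # neither of its records may train the model
  ph <- dplyr::bind_rows(
    make_records("a1", "T1", "S1", 1, 1.0),
    make_records("a1", "T2", "S1", 1, 1.2),
    make_records(sprintf("b%d", 1:8), "T1", "S1", 1, rnorm(8)),
    make_records(sprintf("c%d", 1:8), "T2", "S1", 1, rnorm(8))
  )
  gr <- cv_grouping(ph, "trial")
  for (sch in c("one_all", "group_all")) {
    f <- cv_folds(sch, gr, folds = 3, seed = 1)
    for (i in seq_len(nrow(f))) {
      if ("a1" %in% f$val_accessions[[i]]) {
        expect_false("a1" %in% f$train_accessions[[i]])
      }
    }
  }
})

test_that("one_all over a single group reproduces one_group exactly", {
  set.seed(5)
  col <- small_collection()
  ph <- dplyr::filter(col$phenotypes, trial == "T01")
  gr <- cv_grouping(ph, "trial")
  gi <- small_panel()
  spec <- wgr_spec("gblup", trait = "oil")
  r1 <- run_scheme("one_group", gr, ph, spec, kinship = gi$K, folds = 4,
                   boot_reps = 200, seed = 9)
  r2 <- run_scheme("one_all", gr, ph, spec, kinship = gi$K, folds = 4,
                   boot_reps = 200, seed = 9)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-12)
  expect_equal(r1$n_train, r2$n_train)
})

test_that("group_all by state is not the average of group_group pairs", {
  pan <- small_panel()
  gr <- cv_grouping(pan$col$phenotypes, "state")
  spec <- wgr_spec("gblup", trait = "oil")
  r_all <- run_scheme("group_all", gr, pan$col$phenotypes, spec,
                      kinship = pan$K, boot_reps = 200, seed = 3)
  r_pair <- run_scheme("group_group", gr, pan$col$phenotypes, spec,
                       kinship = pan$K, boot_reps = 200, seed = 3)
  pair_means <- r_pair |>
    dplyr::group_by(group) |>
    dplyr::summarise(r = mean(r, na.rm = TRUE))
  merged <- dplyr::inner_join(tibble::as_tibble(r_all), pair_means, by = "group",
                              suffix = c("_all", "_pair"))
  expect_gt(max(abs(merged$r_all - merged$r_pair)), 1e-6)
})

test_that("small validation groups report undefined ability, not a crash", {
  set.seed(30)
  ph <- dplyr::bind_rows(
    make_records(sprintf("a%d", 1:20), "T1", "S1", 1, rnorm(20)),
    make_records(sprintf("z%d", 1:2), "T2", "S1", 1, rnorm(2)),
    make_records(sprintf("c%d", 1:15), "T3", "S1", 1, rnorm(15))
  )
  dos <- random_inbred_panel(37, 60, seed = 31)
  rownames(dos) <- c(sprintf("a%d", 1:20), sprintf("z%d", 1:2),
                     sprintf("c%d", 1:15))
  K <- compute_grm(geno_matrix(dos))
  gr <- cv_grouping(ph, "trial")
  rep <- run_scheme("group_all", gr, ph, wgr_spec("gblup", trait = "oil"),
                    kinship = K, boot_reps = 100, seed = 4)
  expect_true(is.na(rep$r[rep$group == "T2"]))
  expect_equal(rep$n_val[rep$group == "T2"], 2)
})

test_that("cv reports carry bootstrap intervals containing the estimate", {
  pan <- small_panel()
  gr <- cv_grouping(pan$col$phenotypes, "trial")
  rep <- run_scheme("group_all", gr, pan$col$phenotypes,
                    wgr_spec("gblup", trait = "oil"), kinship = pan$K,
                    boot_reps = 500, seed = 6)
  ok <- !is.na(rep$r)
  expect_true(all(rep$ci_low[ok] <= rep$r[ok] & rep$r[ok] <= rep$ci_high[ok]))
  expect_true(all(rep$n_val[ok] >= 3))
  gl <- glance(rep)
  expect_equal(gl$n_groups, nrow(rep))
})

test_that("autoplot methods return ggplot objects", {
  pan <- small_panel()
  gr <- cv_grouping(pan$col$phenotypes, "trial")
  rep <- run_scheme("group_all", gr, pan$col$phenotypes,
                    wgr_spec("gblup", trait = "oil"), kinship = pan$K,
                    boot_reps = 100, seed = 2)
  expect_s3_class(autoplot(rep), "ggplot")
  d <- fit_fixed_effects(pan$col$phenotypes, "oil")
  adj <- adjust_phenotypes(pan$col$phenotypes, d)
  fit <- fit_gblup(adj, pan$K, wgr_spec("gblup", trait = "oil"))
  expect_s3_class(autoplot(fit), "ggplot")
})
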