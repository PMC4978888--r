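#' Configure a synthetic germplasm collection
#'
#' Defines the statistical structure of a simulated diversity panel shaped
#' like a large inbred germplasm collection evaluated across historical field
#' trials: several genetically differentiated clusters of fully inbred lines,
#' maturity groups correlated with cluster, trials nested in states with
#' latitude-driven maturity-group bands, heritable oil/protein/yield, and
#' lodging/shattering scores (1-5) that penalize machine-harvestable yield.
#'
#' Traits are simulated on a standardized within-trial scale (unit non-fixed
#' variance) and then shifted/scaled to field units: oil and protein in
#' percent seed content, yield in Mg/ha.
#'
#' @param n_accessions Number of inbred accessions.
#' @param p_markers Number of biallelic markers.
#' @param n_clusters Number of genetic clusters (default 9).
#' @param fst Cluster differentiation in (0, 1) for the Balding-Nichols
#'   frequency model (default 0.15).
#' @param n_trials,n_states Trial and state counts (defaults 25 and 3).
#' @param mg_levels Number of maturity-group classes, labelled `0 ..
#'   mg_levels - 1` (default 10).
#' @param architecture `"infinitesimal"` (all markers contribute) or
#'   `"sparse"` (only `n_qtl` markers).
#' @param n_qtl Number of causal markers under the sparse architecture.
#' @param h2 Named per-trait heritabilities on the record level (variance of
#'   the genetic value over the non-fixed variance).
#' @param trial_effect_sd,mg_effect_sd SDs of trial effects and of
#'   maturity-group-within-trial effects (standardized scale).
#' @param gxe_sd SD of independent trial-by-accession interaction draws.
#' @param prop_two_trials Fraction of accessions evaluated in two trials
#'   (the rest are evaluated once).
#' @param gamma_lodging,gamma_shattering Per-score-point yield penalties
#'   (standardized scale); the defaults are calibrated so pooled within-trial
#'   correlations of yield with lodging and shattering come out near -0.21
#'   and -0.27.
#' @param score_h2 Heritability of the latent lodging/shattering scores
#'   (default 0.8: harvest-loss scores are genetically much simpler than
#'   yield itself, so raw machine-harvest yield prediction is partly score
#'   prediction).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param seed Integer seed; all outputs are bit-reproducible given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 1000, p_markers = 2000,
                       n_clusters = 9, fst = 0.15,
                       n_trials = 25, n_states = 3, mg_levels = 10,
                       architecture = c("infinitesimal", "sparse"),
                       n_qtl = 20,
                       h2 = c(oil = 0.6, protein = 0.6, yield = 0.4),
                       trial_effect_sd = 0.5, mg_effect_sd = 0.3,
                       gxe_sd = 0.2, prop_two_trials = 0.15,
                       gamma_lodging = 0.165, gamma_shattering = 0.21,
                       score_h2 = 0.8, missing_rate = 0, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(fst > 0, fst < 1, all(h2 >= 0), all(h2 <= 1),
            n_qtl <= p_markers, missing_rate >= 0, missing_rate < 1,
            trial_effect_sd >= 0, mg_effect_sd >= 0, gxe_sd >= 0,
            prop_two_trials >= 0, prop_two_trials <= 1)
  structure(
    list(n_accessions = n_accessions, p_markers = p_markers,
         n_clusters = n_clusters, fst = fst, n_trials = n_trials,
         n_states = n_states, mg_levels = mg_levels,
         architecture = architecture, n_qtl = n_qtl, h2 = h2,
         trial_effect_sd = trial_effect_sd, mg_effect_sd = mg_effect_sd,
         gxe_sd = gxe_sd, prop_two_trials = prop_two_trials,
         gamma_lodging = gamma_lodging, gamma_shattering = gamma_shattering,
         score_h2 = score_h2, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# trait units: intercept and scale taking the standardized record value to
# field units
trait_units <- function() {
  tibble::tribble(
    ~trait,    ~mean, ~scale,
    "oil",      19.5,   1.2,
    "protein",  41.0,   1.8,
    "yield",     2.5,   0.45
  )
}

#' Simulate structured inbred genotypes
#'
#' Balding-Nichols model: ancestral frequencies are Uniform(0.05, 0.95);
#' cluster frequencies are Beta draws around them with differentiation `fst`;
#' each accession receives sparse, cluster-dominant admixture proportions
#' (Dirichlet) and fully inbred dosages in \{0, 2\} drawn at its admixed
#' frequency. An outbred Hardy-Weinberg mode (`inbred = FALSE`, dosages
#' Binomial(2, freq)) exists for relationship-matrix diagnostics.
#'
#' @param cfg A [sim_config()].
#' @param inbred Draw fully inbred dosages (default) or outbred HWE dosages.
#' @return A list: `genotypes` ([geno_matrix()]), `clusters` (tibble
#'   `accession_id`, `cluster`), `membership` (tibble of admixture
#'   proportions, rows summing to 1).
#' @export
simulate_genotypes <- function(cfg, inbred = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions; p <- cfg$p_markers; K <- cfg$n_clusters
  F <- cfg$fst

  anc <- stats::runif(p, 0.05, 0.95)
  # cluster frequencies: Beta(theta (1-F)/F, (1-theta)(1-F)/F)
  cl_freq <- matrix(stats::rbeta(K * p,
                                 rep(anc, each = K) * (1 - F) / F,
                                 rep(1 - anc, each = K) * (1 - F) / F),
                    nrow = K)

  # sparse cluster-dominant admixture
  dominant <- sample.int(K, n, replace = TRUE)
  alpha <- matrix(0.1, n, K)
  alpha[cbind(seq_len(n), dominant)] <- 6
  q <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  q <- q / rowSums(q)

  freq <- q %*% cl_freq                       # n x p admixed frequencies
  freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
  dos <- if (inbred) {
    2 * matrix(stats::rbinom(n * p, 1, freq), n, p)
  } else {
    matrix(stats::rbinom(n * p, 2, freq), n, p)
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    dos[mask] <- NA_real_
  }
  ids <- sprintf("PI%05d", seq_len(n))
  rownames(dos) <- ids
  colnames(dos) <- sprintf("snp%05d", seq_len(p))

  membership <- tibble::as_tibble(as.data.frame(q))
  names(membership) <- sprintf("cluster%d", seq_len(K))
  membership <- dplyr::bind_cols(tibble::tibble(accession_id = ids), membership)

  list(
    genotypes = geno_matrix(dos),
    clusters = tibble::tibble(accession_id = ids,
                              cluster = sprintf("cluster%d", max.col(q, "first"))),
    membership = membership
  )
}

#' Simulate the trial design of a germplasm evaluation program
#'
#' Maturity groups are drawn around cluster-specific means (early clusters
#' are early-maturing), so MG correlates with genetic cluster. States occupy
#' overlapping latitude bands of maturity groups — the northernmost state
#' hosts only early MGs, the southernmost only late MGs — and each trial,
#' nested in a state, accepts a contiguous MG window inside its state band.
#' Most accessions are evaluated in a single trial; a minority in two.
#'
#' @param cfg A [sim_config()].
#' @param clusters Tibble `accession_id`, `cluster` from
#'   [simulate_genotypes()].
#' @return A list: `accessions` (tibble `accession_id`, `cluster`,
#'   `maturity_group`), `trials` (tibble `trial`, `state`, `mg_min`,
#'   `mg_max`), `assignments` (tibble `accession_id`, `trial`, `state`,
#'   `maturity_group`).
#' @export
simulate_trial_design <- function(cfg, clusters) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  K <- cfg$n_clusters
  mg_max_level <- cfg$mg_levels - 1L

  cl_idx <- as.integer(sub("^cluster", "", clusters$cluster))
  cl_mean_mg <- (seq_len(K) - 1) * mg_max_level / max(K - 1, 1)
  mg <- round(stats::rnorm(nrow(clusters), cl_mean_mg[cl_idx], 1.2))
  mg <- pmin(pmax(mg, 0L), mg_max_level)

  # state latitude bands over the MG range, overlapping at the edges
  band_width <- mg_max_level / cfg$n_states + 1.5
  band_start <- seq(0, mg_max_level - band_width, length.out = cfg$n_states)
  states <- sprintf("S%d", seq_len(cfg$n_states))

  trial_state_idx <- rep_len(seq_len(cfg$n_states), cfg$n_trials)
  trial_tab <- tibble::tibble(
    trial = sprintf("T%02d", seq_len(cfg$n_trials)),
    state = states[trial_state_idx],
    mg_min = floor(band_start[trial_state_idx]),
    mg_max = ceiling(band_start[trial_state_idx] + band_width)
  )

  # candidate trials per accession = trials whose MG window covers its MG
  acc_tab <- tibble::tibble(accession_id = clusters$accession_id,
                            cluster = clusters$cluster, maturity_group = mg)
  n_trials_per_acc <- 1L + stats::rbinom(nrow(acc_tab), 1L, cfg$prop_two_trials)
  assign_rows <- vector("list", nrow(acc_tab))
  for (i in seq_len(nrow(acc_tab))) {
    ok <- which(trial_tab$mg_min <= mg[i] & trial_tab$mg_max >= mg[i])
    if (length(ok) == 0) {
      stop("infeasible maturity-group bands: MG ", mg[i],
           " fits no trial window", call. = FALSE)
    }
    chosen <- sample(ok, min(n_trials_per_acc[i], length(ok)))
    assign_rows[[i]] <- tibble::tibble(
      accession_id = acc_tab$accession_id[i],
      trial = trial_tab$trial[chosen],
      state = trial_tab$state[chosen],
      maturity_group = mg[i]
    )
  }
  list(accessions = acc_tab, trials = trial_tab,
       assignments = dplyr::bind_rows(assign_rows))
}

# draw marker effects for one trait and scale them so the accession-level
# genetic values have exactly unit-h2 variance on the standardized scale
draw_scaled_effects <- function(Xc, architecture, n_qtl, h2) {
  p <- ncol(Xc)
  b <- if (architecture == "sparse") {
    bb <- numeric(p)
    qtl <- sample.int(p, n_qtl)
    bb[qtl] <- stats::rnorm(n_qtl)
    bb
  } else {
    stats::rnorm(p)
  }
  g <- drop(Xc %*% b)
  s <- stats::sd(g)
  if (s == 0 || h2 == 0) {
    b <- b * 0; g <- g * 0
  } else {
    f <- sqrt(h2) / s
    b <- b * f; g <- g * f
  }
  names(b) <- colnames(Xc)
  names(g) <- rownames(Xc)
  list(b = b, g = g)
}

#' Simulate phenotype records and their generating truth
#'
#' Record values follow `value = mu_trait + scale * (e_j + m_k(j) + g_i +
#' gxe_ij + eps)`, with marker effects drawn per architecture and scaled so
#' the genetic variance equals `h2` against unit non-fixed variance. Lodging
#' and shattering arise from heritable latent scores discretized into five
#' equiprobable classes; the recorded yield is machine-harvestable:
#' yield potential minus per-score-point penalties for lodging and
#' shattering.
#'
#' @param cfg A [sim_config()].
#' @param geno A [geno_matrix()] from [simulate_genotypes()] (missing calls
#'   are mean-imputed internally for the genetic values).
#' @param design Output of [simulate_trial_design()].
#' @return A list: `phenotypes` (record tibble with `lodging`/`shattering`
#'   on yield records) and `truth` (list with per-trait `marker_effects`,
#'   `genetic_values`, `h2`, `trial_effects`, `mg_effects`, plus the latent
#'   score components).
#' @export
simulate_phenotypes <- function(cfg, geno, design) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "geno_matrix"))
  set.seed(cfg$seed + 2L)
  dos <- geno$dosages
  if (anyNA(dos)) dos <- impute_missing(geno)$dosages
  Xc <- sweep(dos, 2, colMeans(dos), "-")
  n <- nrow(Xc)
  ids <- rownames(dos)
  asg <- design$assignments
  units <- trait_units()

  traits <- c("oil", "protein", "yield")
  eff <- purrr::map(stats::setNames(traits, traits), function(tr) {
    draw_scaled_effects(Xc, cfg$architecture, cfg$n_qtl, cfg$h2[[tr]])
  })

  # latent machine-harvest nuisance scores (heritable, independent of the
  # yield-potential genetics)
  score_latent <- purrr::map(c(lodging = "lodging", shattering = "shattering"),
    function(sc) {
      gl <- draw_scaled_effects(Xc, "infinitesimal", cfg$n_qtl, cfg$score_h2)
      latent <- gl$g + stats::rnorm(n, 0, sqrt(1 - cfg$score_h2))
      score <- cut(latent, breaks = c(-Inf, stats::qnorm(c(.2, .4, .6, .8),
                                                         mean = mean(latent),
                                                         sd = stats::sd(latent)), Inf),
                   labels = FALSE)
      list(latent = latent, score = as.integer(score), b = gl$b)
    })

  trial_effects <- stats::setNames(
    stats::rnorm(cfg$n_trials, 0, cfg$trial_effect_sd), design$trials$trial)
  mg_cells <- dplyr::distinct(asg, .data$trial, .data$maturity_group)
  mg_effects <- mg_cells |>
    dplyr::mutate(effect = stats::rnorm(dplyr::n(), 0, cfg$mg_effect_sd))

  acc_idx <- match(asg$accession_id, ids)
  rec_base <- asg |>
    dplyr::left_join(mg_effects, by = c("trial", "maturity_group")) |>
    dplyr::mutate(e_j = unname(trial_effects[.data$trial]))

  rec_list <- purrr::map(traits, function(tr) {
    h2 <- cfg$h2[[tr]]
    eps_sd <- sqrt(max(1 - h2 - cfg$gxe_sd^2, 0))
    gxe <- stats::rnorm(nrow(rec_base), 0, cfg$gxe_sd)
    eps <- stats::rnorm(nrow(rec_base), 0, eps_sd)
    std <- rec_base$e_j + rec_base$effect + unname(eff[[tr]]$g[acc_idx]) +
      gxe + eps
    if (tr == "yield") {
      lod <- score_latent$lodging$score[acc_idx]
      shat <- score_latent$shattering$score[acc_idx]
      std <- std - cfg$gamma_lodging * (lod - 1) - cfg$gamma_shattering * (shat - 1) +
        stats::rnorm(nrow(rec_base), 0, 0.1)
    }
    u <- units[units$trait == tr, ]
    out <- rec_base |>
      dplyr::transmute(.data$accession_id, .data$trial, .data$state,
                       maturity_group = as.character(.data$maturity_group),
                       trait = tr, value = u$mean + u$scale * std)
    if (tr == "yield") {
      out$lodging <- score_latent$lodging$score[acc_idx]
      out$shattering <- score_latent$shattering$score[acc_idx]
    } else {
      out$lodging <- NA_integer_
      out$shattering <- NA_integer_
    }
    out
  })
  phenotypes <- validate_phenotypes(dplyr::bind_rows(rec_list))

  truth <- list(
    marker_effects = purrr::map(eff, "b"),
    genetic_values = purrr::map(eff, ~ stats::setNames(.x$g, ids)),
    h2 = cfg$h2,
    trial_effects = trial_effects,
    mg_effects = mg_effects,
    score_marker_effects = purrr::map(score_latent, "b"),
    scores = purrr::map(score_latent, "score"),
    trait_units = units
  )
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate a complete synthetic germplasm collection
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_trial_design()] and [simulate_phenotypes()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes`, `clusters`, `membership`, `design`,
#'   `phenotypes` and `truth`.
#' @export
simulate_collection <- function(cfg = sim_config()) {
  gen <- simulate_genotypes(cfg)
  design <- simulate_trial_design(cfg, gen$clusters)
  ph <- simulate_phenotypes(cfg, gen$genotypes, design)
  list(genotypes = gen$genotypes, clusters = gen$clusters,
       membership = gen$membership, design = design,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
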