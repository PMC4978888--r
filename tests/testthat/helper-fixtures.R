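# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small but structured collection used across modules
small_collection <- function() {
  memo("small_collection", simulate_collection(
    sim_config(n_accessions = 250, p_markers = 500, n_trials = 6,
               n_clusters = 5, seed = 42)
  ))
}

small_panel <- function() {
  memo("small_panel", {
    col <- small_collection()
    qc <- filter_markers(col$genotypes)
    gi <- impute_missing(qc$genotypes)
    list(col = col, geno = gi, K = compute_grm(gi))
  })
}

# brute-force double-loop evaluation of the per-marker-standardized GRM
grm_oracle <- function(dos, theta = colSums(dos) / (2 * nrow(dos))) {
  n <- nrow(dos); p <- ncol(dos)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (l in seq_len(p)) {
        s <- s + (dos[i, l] - 2 * theta[l]) * (dos[j, l] - 2 * theta[l]) /
          (2 * theta[l] * (1 - theta[l]))
      }
      G[i, j] <- s / p
    }
  }
  G
}

# random polymorphic inbred panel for oracle checks
random_inbred_panel <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    freq <- runif(p, 0.1, 0.9)
    dos <- 2 * matrix(rbinom(n * p, 1, rep(freq, each = n)), n, p)
    dimnames(dos) <- list(sprintf("acc%03d", seq_len(n)),
                          sprintf("mk%04d", seq_len(p)))
    theta <- colSums(dos) / (2 * n)
    if (all(theta > 0 & theta < 1)) return(dos)
  }
}

# ridge-regression marker BLUP matching G-BLUP with G = W W' / p: solves the
# dense mixed-model equations directly (independent of the package's
# eigendecomposition path)
ridge_oracle_predict <- function(W_train, y_train, lambda, W_new) {
  p <- ncol(W_train)
  n <- nrow(W_train)
  X <- cbind(1, W_train)
  # joint normal equations for (intercept, b) with penalty lambda * p on b
  P <- diag(c(0, rep(lambda * p, p)))
  sol <- solve(crossprod(X) + P, crossprod(X, y_train))
  mu <- sol[1]
  b <- sol[-1]
  list(mu = mu, fitted = unname(drop(mu + W_train %*% b)),
       pred = unname(drop(mu + W_new %*% b)))
}

# simple record table builder
make_records <- function(accession_id, trial, state, mg, value,
                         trait = "oil", lodging = NA_integer_,
                         shattering = NA_integer_) {
  tibble::tibble(accession_id = accession_id, trial = trial, state = state,
                 maturity_group = as.character(mg), trait = trait,
                 value = value, lodging = lodging, shattering = shattering)
}
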