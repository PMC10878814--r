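# Independent oracles used across the suite. These deliberately avoid the
# package's analytic formulas: densities are renormalized by adaptive
# quadrature and ML optima are found by grid search, so agreement is a
# genuine cross-check.

# Step weight as a plain function of y (independent re-statement).
oracle_weight_fn <- function(se, spec, omega) {
  switch(spec$mechanism,
         none = function(y) rep(1, length(y)),
         sign = function(y) ifelse(y > 0, 1, omega),
         alpha = {
           if (spec$sidedness == "two_sided") {
             cut <- qnorm(1 - spec$alpha_level / 2) * se
             function(y) ifelse(abs(y) > cut, 1, omega)
           } else {
             cut <- qnorm(1 - spec$alpha_level) * se
             function(y) ifelse(y > cut, 1, omega)
           }
         })
}

# Cutpoints where the step weight jumps (for piecewise quadrature).
oracle_cutpoints <- function(se, spec) {
  switch(spec$mechanism,
         none = numeric(0),
         sign = 0,
         alpha = {
           if (spec$sidedness == "two_sided") {
             cut <- qnorm(1 - spec$alpha_level / 2) * se
             c(-cut, cut)
           } else qnorm(1 - spec$alpha_level) * se
         })
}

# Plain mixture marginal density for one se.
oracle_mixture_fn <- function(se, params) {
  function(y) {
    out <- 0
    for (k in seq_len(params$K))
      out <- out + params$weights[k] *
        dnorm(y, params$means[k], sqrt(params$taus[k]^2 + se^2))
    out
  }
}

# Expected selection weight by piecewise adaptive quadrature.
oracle_normalizing_constant <- function(se, params, spec, omega) {
  w <- oracle_weight_fn(se, spec, omega)
  mixf <- oracle_mixture_fn(se, params)
  pts <- sort(oracle_cutpoints(se, spec))
  edges <- c(-Inf, pts, Inf)
  total <- 0
  for (j in seq_len(length(edges) - 1L))
    total <- total + integrate(function(y) w(y) * mixf(y),
                               edges[j], edges[j + 1L],
                               rel.tol = 1e-10, abs.tol = 1e-12)$value
  total
}

# Quadrature-renormalized weighted mixture density.
oracle_density <- function(y, se, params, spec) {
  omega <- params$omega
  w <- oracle_weight_fn(se, spec, omega)
  mixf <- oracle_mixture_fn(se, params)
  A <- oracle_normalizing_constant(se, params, spec, omega)
  w(y) * mixf(y) / A
}

# Integral of the package's observed density over the real line, split at
# the weight-function discontinuities.
oracle_density_integral <- function(se, params, spec) {
  pts <- sort(oracle_cutpoints(se, spec))
  edges <- c(-Inf, pts, Inf)
  total <- 0
  for (j in seq_len(length(edges) - 1L))
    total <- total + integrate(
      function(y) observed_density(y, rep(se, length(y)), params, spec),
      edges[j], edges[j + 1L], rel.tol = 1e-9, abs.tol = 1e-12)$value
  total
}

# Coarse-to-fine grid-search ML for the K = 1 no-selection model.
oracle_grid_fit_K1 <- function(dataset, n_grid = 200L, n_refine = 3L) {
  y <- dataset$effect
  mu_lo <- min(y); mu_hi <- max(y)
  tau_lo <- 0; tau_hi <- 2 * sd(y)
  spec <- model_spec(1)
  best <- c(NA, NA, -Inf)
  for (r in seq_len(n_refine)) {
    mus <- seq(mu_lo, mu_hi, length.out = n_grid)
    taus <- seq(tau_lo, tau_hi, length.out = n_grid)
    ll <- matrix(NA_real_, n_grid, n_grid)
    for (i in seq_len(n_grid)) {
      s <- sqrt(outer(dataset$se^2, taus^2, `+`))
      lphi <- dnorm(y, mus[i], s, log = TRUE)
      ll[i, ] <- colSums(lphi)
    }
    idx <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    best <- c(mus[idx[1L]], taus[idx[2L]], max(ll))
    dmu <- (mu_hi - mu_lo) / (n_grid - 1L)
    dtau <- (tau_hi - tau_lo) / (n_grid - 1L)
    mu_lo <- best[1L] - 2 * dmu; mu_hi <- best[1L] + 2 * dmu
    tau_lo <- max(0, best[2L] - 2 * dtau); tau_hi <- best[2L] + 2 * dtau
  }
  list(mu = best[1L], tau = best[2L], loglik = best[3L])
}

# Random valid parameter/mechanism draws for property tests.
random_params_spec <- function(K = sample(1:3, 1L),
                               with_selection = TRUE) {
  g <- rgamma(K, 2)
  mech <- if (with_selection)
    sample(list(sel_sign(), sel_alpha(0.10), sel_alpha(0.05),
                sel_alpha(0.10, sidedness = "one_sided")), 1L)[[1L]]
  else sel_none()
  params <- mixture_params(
    weights = g / sum(g),
    means = sort(runif(K, -4, 4)),
    taus = runif(K, 0, 3),
    omega = if (mech$mechanism == "none") 1 else runif(1, 0.05, 0.95))
  list(params = params, spec = mech, se = exp(runif(1, log(0.2), log(3))))
}

# Small deterministic dataset used by several files.
toy_dataset <- function(n = 20L, seed = 11L) {
  simulate_dataset(sim_config(
    truth = mixture_params(c(0.5, 0.5), c(0, 2), c(0.5, 1)),
    n_target = n, seed = seed))$dataset
}
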