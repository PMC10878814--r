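test_that("transform/untransform round-trips parameters", {
  sp <- model_spec(2, selection = sel_sign())
  p <- mixture_params(c(0.5, 0.5), c(0, 1), c(1, 1), omega = 0.5)
  back <- untransform_params(transform_params(p, sp), sp)
  expect_equal(back$weights, p$weights, tolerance = 1e-10)
  expect_equal(back$means, p$means, tolerance = 1e-10)
  expect_equal(back$taus, p$taus, tolerance = 1e-10)
  expect_equal(back$omega, p$omega, tolerance = 1e-10)
  # K = 1: no weight block, p = 2 (+1 with selection)
  expect_length(transform_params(mixture_params(1, 0, 1), model_spec(1)), 2)
  expect_identical(model_spec(1, selection = sel_sign())$p, 3L)
})

test_that("round-trip error stays below 1e-8 over 1000 random draws", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    K <- sample(1:3, 1)
    g <- rgamma(K, 2)
    has_sel <- i %% 2 == 0
    p <- mixture_params(g / sum(g), sort(rnorm(K, 0, 3)),
                        runif(K, 1e-4, 4),
                        omega = if (has_sel) runif(1, 0.01, 0.99) else 1)
    sp <- model_spec(K, selection = if (has_sel) sel_sign() else sel_none())
    b <- untransform_params(transform_params(p, sp), sp)
    worst <- max(worst,
                 abs(b$weights - p$weights), abs(b$means - p$means),
                 abs(b$taus - p$taus), abs(b$omega - p$omega))
  }
  expect_lt(worst, 1e-8)
})

test_that("non-finite parameter vectors are rejected", {
  sp <- model_spec(1)
  expect_error(untransform_params(c(NA, 0), sp), "non-finite")
  expect_error(untransform_params(c(Inf, 0), sp), "non-finite")
  expect_error(untransform_params(1, sp), "length")
})

test_that("analytic gradient matches central differences", {
  ds <- toy_dataset(40, seed = 21)
  num_grad <- function(fn, v, h = 1e-6)
    vapply(seq_along(v), function(i) {
      e <- numeric(length(v)); e[i] <- h
      (fn(v + e) - fn(v - e)) / (2 * h)
    }, numeric(1))
  set.seed(88)
  specs <- list(model_spec(1), model_spec(3),
                model_spec(2, selection = sel_sign()),
                model_spec(2, selection = sel_alpha(0.10)),
                model_spec(1, selection = sel_alpha(0.05,
                                                    sidedness = "one_sided")))
  for (sp in specs) {
    v <- rnorm(sp$p, 0, 0.7)
    fn <- function(v) log_likelihood(ds, sp, untransform_params(v, sp))
    expect_equal(selmix:::loglik_grad(v, ds, sp), num_grad(fn, v),
                 tolerance = 1e-5)
  }
})

test_that("K = 1 ML fit matches the grid-search oracle and a known truth", {
  set.seed(5)
  y <- rnorm(200, 1.4, sqrt(1 + 1))  # tau = 1 on top of se = 1
  ds <- effect_dataset(effect = y, se = rep(1, 200))
  fit <- fit_model(ds, model_spec(1), fit_config(n_starts = 8, seed = 2))
  grid <- oracle_grid_fit_K1(ds)
  expect_lt(abs(fit$loglik - grid$loglik), 1e-3)
  expect_lt(abs(fit$params_hat$means - grid$mu), 1e-3)
  expect_lt(abs(fit$params_hat$taus - grid$tau), 1e-3)
  se_mu <- sqrt(2 / 200)  # marginal SD sqrt(2) over sqrt(n)
  expect_lt(abs(fit$params_hat$means - 1.4), 3 * se_mu)
})

test_that("K = 1 estimates agree with grid search on 10 random small datasets", {
  set.seed(99)
  for (i in 1:10) {
    sim <- simulate_dataset(sim_config(
      truth = mixture_params(1, runif(1, -1, 2), runif(1, 0.2, 1.5)),
      n_target = 100, seed = 1000 + i))
    fit <- fit_model(sim$dataset, model_spec(1),
                     fit_config(n_starts = 6, seed = i))
    grid <- oracle_grid_fit_K1(sim$dataset)
    expect_lt(abs(fit$params_hat$means - grid$mu), 1e-3)
    expect_lt(abs(fit$params_hat$taus - grid$tau), 1e-3)
  }
})

test_that("K = 1 fit cross-checks against metafor's ML random-effects fit", {
  skip_if_not_installed("metafor")
  sim <- simulate_dataset(sim_config(
    truth = mixture_params(1, 1.2, 0.8), n_target = 150, seed = 77))
  fit <- fit_model(sim$dataset, model_spec(1),
                   fit_config(n_starts = 6, seed = 3))
  rma <- metafor::rma(yi = sim$dataset$effect, sei = sim$dataset$se,
                      method = "ML")
  expect_equal(fit$params_hat$means, as.numeric(rma$beta), tolerance = 1e-4)
  expect_equal(fit$params_hat$taus, sqrt(rma$tau2), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(rma)), tolerance = 1e-5)
})

test_that("BIC arithmetic is exact and consistent with stored fits", {
  expect_equal(compute_bic(-100, 2, 241), 2 * log(241) + 200)
  expect_equal(compute_bic(0, 0, 10), 0)
  sim <- simulate_dataset(sim_config(n_target = 60, seed = 12))
  fit <- fit_model(sim$dataset, model_spec(2),
                   fit_config(n_starts = 4, seed = 4))
  expect_identical(fit$bic, compute_bic(fit$loglik, fit$p, fit$n))
})

test_that("fits fail cleanly when parameters outnumber effects", {
  ds <- effect_dataset(effect = c(1, 2), se = c(1, 1))
  expect_error(fit_model(ds, model_spec(2)), "more effects")
})

test_that("fitting is deterministic given the seed", {
  ds <- toy_dataset(50, seed = 8)
  sp <- model_spec(2, selection = sel_sign())
  f1 <- fit_model(ds, sp, fit_config(n_starts = 4, seed = 9))
  f2 <- fit_model(ds, sp, fit_config(n_starts = 4, seed = 9))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params_hat, f2$params_hat)
  expect_identical(f1$best_start_index, f2$best_start_index)
})

test_that("model nesting is respected by the optimizer", {
  sim <- simulate_dataset(sim_config(
    truth = mixture_params(c(0.6, 0.4), c(0, 3), c(0.5, 1.5)),
    selection = sel_sign(), n_target = 150, seed = 14))
  ds <- sim$dataset
  cfg <- fit_config(n_starts = 6, seed = 15)
  f1 <- fit_model(ds, model_spec(1), cfg)
  f2 <- fit_model(ds, model_spec(2), cfg,
                  extra_starts = list(selmix:::split_component(f1$params_hat)))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  warm <- list(mixture_params(f1$params_hat$weights, f1$params_hat$means,
                              pmax(f1$params_hat$taus, 1e-6),
                              omega = 1 - 1e-9))
  f1s <- fit_model(ds, model_spec(1, selection = sel_sign()), cfg,
                   extra_starts = warm)
  expect_gte(f1s$loglik, f1$loglik - 1e-6)
})

test_that("recovery from a known 2-mixture with sign selection", {
  truth <- mixture_params(c(0.6, 0.4), c(0.5, 3), c(0.6, 2.5), omega = 0.3)
  sim <- simulate_dataset(sim_config(truth = truth,
                                     selection = sel_sign(),
                                     n_target = 1000, seed = 31))
  fit <- fit_model(sim$dataset, model_spec(2, selection = sel_sign()),
                   fit_config(n_starts = 6, seed = 32))
  expect_equal(fit$params_hat$means, truth$means, tolerance = 0.35)
  expect_equal(fit$params_hat$omega, truth$omega, tolerance = 0.25)
  expect_true(fit$converged)
})
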