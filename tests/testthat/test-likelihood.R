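test_that("step selection weight matches its definition per mechanism", {
  expect_equal(selection_weight(2, 1, sel_sign(), 0.3), 1)
  expect_equal(selection_weight(-2, 1, sel_sign(), 0.3), 0.3)
  expect_equal(selection_weight(0, 1, sel_sign(), 0.3), 0.3)  # y > 0 strict
  expect_equal(selection_weight(c(-5, 7), c(1, 2), sel_none(), 1), c(1, 1))
  # z(0.95) = 1.6449: 1.7 is significant at alpha = 0.10 two-sided, 1.6 not
  expect_equal(selection_weight(1.7, 1, sel_alpha(0.10), 0.5), 1)
  expect_equal(selection_weight(1.6, 1, sel_alpha(0.10), 0.5), 0.5)
  expect_equal(selection_weight(-1.7, 1, sel_alpha(0.10), 0.5), 1)
  # one-sided: the negative tail is never "significant"
  one <- sel_alpha(0.10, sidedness = "one_sided")
  expect_equal(selection_weight(-9, 1, one, 0.5), 0.5)
  expect_equal(selection_weight(1.3, 1, one, 0.5), 1)  # z(0.90) = 1.2816
})

test_that("component marginal SD combines tau and se in quadrature", {
  expect_equal(component_marginal_sd(0, 2), 2)
  expect_equal(component_marginal_sd(3, 4), 5)
  expect_equal(component_marginal_sd(1.5, 0.7), sqrt(1.5^2 + 0.7^2))
  expect_gte(component_marginal_sd(1.2, 0.4), 1.2)
})

test_that("normalizing constant has its closed-form special cases", {
  p1 <- mixture_params(1, 0, 0, omega = 1)
  expect_equal(normalizing_constant(c(0.5, 1, 2), p1, sel_sign()),
               rep(1, 3))
  expect_equal(normalizing_constant(1, p1, sel_none()), 1)
  # symmetric spike at 0 under sign selection: A = 0.5 + 0.5 * omega
  p2 <- mixture_params(1, 0, 0, omega = 0.5)
  expect_equal(normalizing_constant(2, p2, sel_sign()), 0.75)
})

test_that("normalizing constant matches piecewise quadrature", {
  p <- mixture_params(c(0.6, 0.4), c(1, -2), c(1, 0.5), omega = 0.2)
  sp <- sel_alpha(0.05)
  expect_equal(normalizing_constant(1, p, sp),
               oracle_normalizing_constant(1, p, sp, 0.2),
               tolerance = 1e-8)
  set.seed(101)
  for (i in 1:10) {
    d <- random_params_spec()
    expect_equal(
      normalizing_constant(d$se, d$params, d$spec),
      oracle_normalizing_constant(d$se, d$params, d$spec, d$params$omega),
      tolerance = 1e-8)
  }
})

test_that("observed density has its known special values and limits", {
  p <- mixture_params(1, 0, 0)
  expect_equal(observed_density(0, 1, p, sel_none()), dnorm(0))
  # omega near 0 suppresses the negative region almost entirely
  p_eps <- mixture_params(1, 0, 0, omega = 1e-9)
  expect_lt(observed_density(-1, 1, p_eps, sel_sign()), 1e-8)
  # no-selection reduction: selection spec with omega = 1 gives the plain
  # mixture marginal
  p2 <- mixture_params(c(0.3, 0.7), c(-1, 2), c(0.5, 1.5))
  y <- seq(-4, 4, by = 0.5)
  expect_equal(observed_density(y, rep(1, length(y)), p2, sel_sign()),
               observed_density(y, rep(1, length(y)), p2, sel_none()))
})

test_that("observed density equals the quadrature-renormalized weighted mixture", {
  p <- mixture_params(c(0.6, 0.4), c(1, -2), c(1, 0.5), omega = 0.2)
  sp <- sel_alpha(0.05)
  y <- seq(-6, 6, by = 0.25)
  expect_equal(observed_density(y, rep(1, length(y)), p, sp),
               oracle_density(y, 1, p, sp), tolerance = 1e-8)
})

test_that("observed density integrates to 1 across random draws", {
  set.seed(202)
  for (i in 1:50) {
    d <- random_params_spec(with_selection = i %% 2 == 0)
    expect_equal(oracle_density_integral(d$se, d$params, d$spec), 1,
                 tolerance = 1e-6)
  }
})

test_that("log-likelihood sums per-record log densities with stable arithmetic", {
  d1 <- effect_dataset(effect = 0, se = 1)
  expect_equal(log_likelihood(d1, model_spec(1), mixture_params(1, 0, 0)),
               log(dnorm(0)))
  # oracle product on a 20-record dataset, selection 2-mixture
  ds <- toy_dataset(20)
  p <- mixture_params(c(0.5, 0.5), c(0, 2), c(0.5, 1), omega = 0.4)
  sp <- model_spec(2, selection = sel_sign())
  oracle_ll <- sum(log(mapply(function(y, se)
    oracle_density(y, se, p, sp$selection), ds$effect, ds$se)))
  expect_equal(log_likelihood(ds, sp, p), oracle_ll, tolerance = 1e-6)
  # dimension mismatch is an error
  expect_error(log_likelihood(ds, model_spec(1), p), "does not match")
})

test_that("selection with omega = 1 reproduces the no-selection log-likelihood exactly", {
  ds <- toy_dataset(30)
  for (K in 1:3) {
    g <- rgamma(K, 2); w <- g / sum(g)
    p_sel <- mixture_params(w, seq_len(K) - 2, rep(0.8, K), omega = 1)
    p_non <- mixture_params(w, seq_len(K) - 2, rep(0.8, K))
    for (m in list(sel_sign(), sel_alpha(0.10), sel_alpha(0.05)))
      expect_identical(
        log_likelihood(ds, model_spec(K, selection = m), p_sel),
        log_likelihood(ds, model_spec(K), p_non))
  }
})

test_that("a mixture of identical components collapses to the K = 1 model", {
  ds <- toy_dataset(30)
  p1 <- mixture_params(1, 0.7, 1.1)
  for (K in 2:3) {
    pK <- mixture_params(rep(1 / K, K), rep(0.7, K), rep(1.1, K))
    expect_equal(log_likelihood(ds, model_spec(K), pK),
                 log_likelihood(ds, model_spec(1), p1), tolerance = 1e-8)
  }
})

test_that("log-likelihood rises as omega falls when all effects are selected", {
  set.seed(33)
  y <- abs(rnorm(40)) + 0.1  # every effect positive: selected under sign
  ds <- effect_dataset(effect = y, se = rep(1, 40))
  sp <- model_spec(1, selection = sel_sign())
  omegas <- c(1, 0.8, 0.5, 0.2, 0.05)
  lls <- vapply(omegas, function(om)
    log_likelihood(ds, sp, mixture_params(1, 0.5, 0.5, omega = om)),
    numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("sign-mechanism log-likelihood is scale-equivariant", {
  ds <- toy_dataset(25)
  p <- mixture_params(c(0.4, 0.6), c(0, 2), c(0.5, 1), omega = 0.3)
  sp <- model_spec(2, selection = sel_sign())
  ll1 <- log_likelihood(ds, sp, p)
  for (c_scale in c(0.5, 2, 7.3)) {
    ds_c <- effect_dataset(effect = c_scale * ds$effect,
                           se = c_scale * ds$se)
    p_c <- mixture_params(p$weights, c_scale * p$means, c_scale * p$taus,
                          omega = p$omega)
    expect_equal(log_likelihood(ds_c, sp, p_c),
                 ll1 - nrow(ds) * log(c_scale), tolerance = 1e-10)
  }
})

test_that("domain-moderated means shift the density by the domain offset", {
  ds <- effect_dataset(effect = c(0.2, 1.2), se = c(1, 1),
                       domain = c("ref", "shift"))
  sp <- model_spec(1, moderated = TRUE, domains = c("ref", "shift"))
  p <- mixture_params(1, 0.2, 0, deltas = c(shift = 1))
  # record 1 sits at the reference mean, record 2 at mean + delta
  expect_equal(log_likelihood(ds, sp, p), 2 * log(dnorm(0)))
  expect_identical(sp$p, 3L)
})
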