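# Maximum-likelihood estimation by multi-start quasi-Newton optimization on
# an unconstrained reparameterization, plus the Schwarz criterion.
#
# Parameterization (in order): component means (identity), log heterogeneity
# SDs (floored at TAU_FLOOR), multinomial-logit mixture weights relative to
# the last component (K - 1 entries, absent for K = 1), logit of omega
# rescaled to [OMEGA_MIN, 1] (only for selection models), and raw domain
# offsets (moderated variant).

TAU_FLOOR <- 1e-8
OMEGA_MIN <- 1e-4

#' Fitting configuration
#'
#' Controls the multi-start optimizer. Starting points are dispersed:
#' candidate means are drawn from data quantiles, heterogeneity SDs from
#' (0.25, 0.5, 1, 2) times the sample SD, mixture weights from a flat
#' Dirichlet, and omega from {0.1, 0.5, 0.9}; all draws are governed by
#' `seed`, so a fit is deterministic given (dataset, spec, config).
#'
#' @param n_starts number of local optimizations (default 20).
#' @param seed integer seed for start-point generation.
#' @param maxit maximum iterations per start.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param grad_tol gradient-norm threshold (transformed scale) below which
#'   the best optimum is flagged as converged.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, seed = 1L, maxit = 2000L,
                       reltol = 1e-10, grad_tol = 1e-6) {
  stopifnot(n_starts >= 1L, maxit >= 1L)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), reltol = reltol,
                 grad_tol = grad_tol),
            class = "fit_config")
}

#' Map parameters to and from the unconstrained scale
#'
#' `transform_params` maps a [mixture_params()] to the unconstrained vector
#' the optimizer works on; `untransform_params` inverts it. The pair is a
#' bijection up to the tau floor (1e-8) and omega bounds [1e-4, 1]:
#' round-tripping interior parameters reproduces them to ~1e-10.
#'
#' @param params a [mixture_params()].
#' @param spec the [model_spec()] the vector is laid out for.
#' @return `transform_params`: numeric vector of length `spec$p`;
#'   `untransform_params`: a [mixture_params()].
#' @export
transform_params <- function(params, spec) {
  check_params_spec(params, spec)
  v <- c(params$means, log(pmax(params$taus, TAU_FLOOR)))
  if (spec$K > 1L) {
    w <- params$weights
    v <- c(v, log(w[-spec$K] / w[spec$K]))
  }
  if (spec$selection$mechanism != "none") {
    om <- min(max(params$omega, OMEGA_MIN), 1 - 1e-12)
    v <- c(v, stats::qlogis((om - OMEGA_MIN) / (1 - OMEGA_MIN)))
  }
  if (spec$moderated)
    v <- c(v, unname(params$deltas[setdiff(spec$domains, spec$domains[1L])]))
  if (length(v) != spec$p) stop_selmix("internal: transform length mismatch")
  v
}

#' @rdname transform_params
#' @param v numeric vector on the unconstrained scale (length `spec$p`).
#' @export
untransform_params <- function(v, spec) {
  raw <- parse_unconstrained(v, spec)
  mixture_params(weights = raw$weights, means = raw$means, taus = raw$taus,
                 omega = raw$omega, deltas = raw$deltas)
}

# Decode the unconstrained vector without canonical component sorting.
parse_unconstrained <- function(v, spec) {
  if (any(!is.finite(v))) stop_selmix("non-finite parameter vector")
  if (length(v) != spec$p) stop_selmix("parameter vector has wrong length")
  K <- spec$K
  means <- v[seq_len(K)]
  taus <- exp(v[K + seq_len(K)])
  i <- 2L * K
  if (K > 1L) {
    z <- c(v[i + seq_len(K - 1L)], 0)
    weights <- exp(z - logsumexp(z))
    i <- i + K - 1L
  } else weights <- 1
  if (spec$selection$mechanism != "none") {
    omega <- OMEGA_MIN + (1 - OMEGA_MIN) * stats::plogis(v[i + 1L])
    i <- i + 1L
  } else omega <- 1
  deltas <- NULL
  if (spec$moderated) {
    nm <- setdiff(spec$domains, spec$domains[1L])
    deltas <- stats::setNames(v[i + seq_along(nm)], nm)
  }
  list(K = K, weights = weights, means = means, taus = taus,
       omega = omega, deltas = deltas)
}

# Analytic gradient of the log-likelihood on the unconstrained scale.
#
# Per record, log f = log w(y) + log M - log A with M the mixture marginal
# density and A the expected selection weight. Writing t_ik = (y_i -
# mu_ik)/s_ik, R_ik = pi_k phi_ik / M_i (posterior responsibilities) and
# A*_ik = omega + (1 - omega) P_ik:
#   d log f / d mu_k  = R_ik t_ik / s_ik - (1-omega) pi_k dP_ik/dmu / A_i
#   d log f / d s_ik  = R_ik (t_ik^2 - 1)/s_ik - (1-omega) pi_k dP/ds / A_i
#   d log f / d pi_k  = phi_ik / M_i - A*_ik / A_i
#   d log f / d omega = 1{suppressed}/omega - sum_k pi_k (1 - P_ik) / A_i
# mapped through the chain rule of the transforms (tau = exp(x), softmax
# weights, rescaled logistic omega). dP/dmu and dP/ds follow from the
# normal CDF of the selected region; see prob_selected().
loglik_grad <- function(v, dataset, spec) {
  # parse v in its own component order (no canonical sort: the likelihood
  # is permutation-invariant but the gradient must match v's layout)
  params <- parse_unconstrained(v, spec)
  K <- spec$K
  y <- dataset$effect
  se <- dataset$se
  n <- length(y)
  has_sel <- spec$selection$mechanism != "none"
  omega <- params$omega
  domain <- if (spec$moderated) dataset$domain
  off <- rep(0, n)
  if (spec$moderated && !is.null(params$deltas)) {
    hit <- domain %in% names(params$deltas)
    off[hit] <- params$deltas[domain[hit]]
  }
  mu <- outer(off, params$means, `+`)            # n x K
  s2 <- outer(se^2, params$taus^2, `+`)
  s <- sqrt(s2)
  tt <- (y - mu) / s
  lphi <- -0.918938533204672742 - log(s) - 0.5 * tt^2  # log dnorm
  lw <- sweep(lphi, 2L, log(params$weights), `+`)
  lM <- if (K == 1L) lw[, 1L] else row_logsumexp(lw)
  R <- exp(lw - lM)                               # responsibilities

  sel <- spec$selection
  if (has_sel) {
    # selected-region probabilities and their mu / s derivatives
    P <- matrix(0, n, K); dPdmu <- matrix(0, n, K); dPds <- matrix(0, n, K)
    for (k in seq_len(K)) {
      if (sel$mechanism == "sign") {
        a <- mu[, k] / s[, k]
        P[, k] <- stats::pnorm(a)
        dPdmu[, k] <- stats::dnorm(a) / s[, k]
        dPds[, k] <- -a * stats::dnorm(a) / s[, k]
      } else if (sel$sidedness == "two_sided") {
        cut <- stats::qnorm(1 - sel$alpha_level / 2) * se
        a <- (-cut - mu[, k]) / s[, k]
        b <- (mu[, k] - cut) / s[, k]
        P[, k] <- stats::pnorm(a) + stats::pnorm(b)
        dPdmu[, k] <- (stats::dnorm(b) - stats::dnorm(a)) / s[, k]
        dPds[, k] <- -(a * stats::dnorm(a) + b * stats::dnorm(b)) / s[, k]
      } else {
        cut <- stats::qnorm(1 - sel$alpha_level) * se
        b <- (mu[, k] - cut) / s[, k]
        P[, k] <- stats::pnorm(b)
        dPdmu[, k] <- stats::dnorm(b) / s[, k]
        dPds[, k] <- -b * stats::dnorm(b) / s[, k]
      }
    }
    Astar <- omega + (1 - omega) * P
    A <- as.numeric(Astar %*% params$weights)
    suppressed <- !selected_region(y, se, sel)
  } else {
    A <- rep(1, n)
  }

  pi_row <- matrix(params$weights, n, K, byrow = TRUE)
  g_mu_ik <- R * tt / s
  g_s_ik <- R * (tt^2 - 1) / s
  if (has_sel) {
    g_mu_ik <- g_mu_ik - (1 - omega) * pi_row * dPdmu / A
    g_s_ik <- g_s_ik - (1 - omega) * pi_row * dPds / A
  }
  g_means <- colSums(g_mu_ik)
  # tau transform: d/dx = d/ds * tau^2 / s (tau = exp(x))
  g_taus <- colSums(g_s_ik * sweep(1 / s, 2L, params$taus^2, `*`))

  g <- c(g_means, g_taus)
  if (K > 1L) {
    U_ik <- R / pi_row
    if (has_sel) U_ik <- U_ik - Astar / A
    U <- colSums(U_ik) - if (has_sel) 0 else n  # sum phi/M - sum A*/A
    # without selection, A* = 1 and A = 1 so the A-term is just n
    piU <- sum(params$weights * U)
    g_z <- params$weights[-K] * (U[-K] - piU)
    g <- c(g, g_z)
  }
  if (has_sel) {
    g_om <- sum(suppressed) / omega -
      sum((1 - P) %*% params$weights / A)
    sig <- (omega - OMEGA_MIN) / (1 - OMEGA_MIN)
    g <- c(g, g_om * (1 - OMEGA_MIN) * sig * (1 - sig))
  }
  if (spec$moderated) {
    base <- rowSums(g_mu_ik)
    nm <- setdiff(spec$domains, spec$domains[1L])
    g <- c(g, vapply(nm, function(d) sum(base[domain == d]), numeric(1)))
  }
  g
}

# Dispersed starting points on the unconstrained scale.
make_starts <- function(dataset, spec, config) {
  y <- dataset$effect
  sdy <- max(stats::sd(y), 1e-3)
  with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(j) {
      if (j == 1L) {
        # deterministic anchor: quantile-spread means, sample-SD taus
        qs <- stats::quantile(y, probs = seq(0.2, 0.8,
                                             length.out = spec$K))
        means <- as.numeric(qs)
        taus <- rep(0.5 * sdy, spec$K)
        weights <- rep(1 / spec$K, spec$K)
        omega <- 0.5
      } else {
        means <- as.numeric(stats::quantile(y, probs = stats::runif(spec$K)))
        taus <- sample(c(0.25, 0.5, 1, 2), spec$K, replace = TRUE) * sdy
        g <- stats::rgamma(spec$K, 1)
        weights <- g / sum(g)
        omega <- sample(c(0.1, 0.5, 0.9), 1L)
      }
      deltas <- if (spec$moderated)
        stats::setNames(rep(0, length(spec$domains) - 1L),
                        setdiff(spec$domains, spec$domains[1L]))
      p0 <- mixture_params(weights = weights, means = means,
                           taus = pmax(taus, 10 * TAU_FLOOR),
                           omega = if (spec$selection$mechanism == "none")
                             1 else omega,
                           deltas = deltas)
      transform_params(p0, spec)
    })
  })
}

#' Fit a model by maximum likelihood
#'
#' Runs `n_starts` BFGS optimizations of the log-likelihood on the
#' unconstrained scale from dispersed starting points and returns the best
#' finite optimum, canonicalized. Deterministic given (dataset, spec,
#' config).
#'
#' @param dataset an [effect_dataset()].
#' @param spec a [model_spec()].
#' @param config a [fit_config()].
#' @param extra_starts optional list of [mixture_params()] used as
#'   additional warm starting points (e.g. the no-selection optimum with
#'   omega near 1 when fitting the nested selection model); appended to the
#'   dispersed starts.
#' @return An object of class `fit_result`: `spec`, `params_hat`, `loglik`,
#'   `n`, `p`, `bic`, `converged`, `n_starts`, `best_start_index`,
#'   `grad_norm`, `optimizer_status`.
#' @export
fit_model <- function(dataset, spec, config = fit_config(),
                      extra_starts = list()) {
  stopifnot(inherits(dataset, "effect_dataset"),
            inherits(spec, "model_spec"),
            inherits(config, "fit_config"))
  n <- attr(dataset, "n_effects")
  if (n <= spec$p)
    stop_selmix("need more effects (", n, ") than parameters (", spec$p, ")")
  negll <- function(v) {
    p <- try(untransform_params(v, spec), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- log_likelihood(dataset, spec, p)
    if (!is.finite(ll)) 1e10 else -ll
  }
  negll_gr <- function(v) {
    g <- try(-loglik_grad(v, dataset, spec), silent = TRUE)
    if (inherits(g, "try-error") || any(!is.finite(g)))
      rep(0, length(v)) else g
  }
  starts <- make_starts(dataset, spec, config)
  if (length(extra_starts))
    starts <- c(starts,
                lapply(extra_starts, transform_params, spec = spec))
  runs <- lapply(starts, function(v0) {
    res <- try(stats::optim(v0, negll, gr = negll_gr, method = "BFGS",
                            control = list(maxit = config$maxit,
                                           reltol = config$reltol)),
               silent = TRUE)
    if (inherits(res, "try-error"))
      list(ok = FALSE, msg = as.character(res))
    else
      list(ok = is.finite(res$value) && res$value < 1e10,
           value = res$value, par = res$par,
           convergence = res$convergence,
           msg = res$message %||% "")
  })
  ok <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(r) r$msg %||% "", character(1))
    stop_selmix("all ", length(starts), " starts failed; diagnostics: ",
                paste(unique(msgs), collapse = " | "))
  }
  values <- vapply(runs, function(r) if (isTRUE(r$ok)) r$value else Inf,
                   numeric(1))
  best <- which.min(values)
  vhat <- runs[[best]]$par
  best_value <- values[best]
  # polish: restart from the incumbent until the objective stops moving,
  # which sharpens nearly-flat directions (small tau, omega near 1)
  for (round in 1:3) {
    pol <- try(stats::optim(vhat, negll, gr = negll_gr, method = "BFGS",
                            control = list(maxit = config$maxit,
                                           reltol = config$reltol)),
               silent = TRUE)
    if (inherits(pol, "try-error") || !is.finite(pol$value)) break
    gain <- best_value - pol$value
    if (pol$value <= best_value) {
      vhat <- pol$par
      best_value <- pol$value
      runs[[best]]$convergence <- pol$convergence
    }
    if (gain < 1e-10) break
  }
  # boundary candidate: a small fitted tau often means the true optimum is
  # the tau = 0 boundary, which the log scale only reaches asymptotically;
  # pin such taus at the floor, re-optimize the rest, keep if not worse
  tau_idx <- spec$K + seq_len(spec$K)
  small <- exp(vhat[tau_idx]) < 0.1
  if (any(small)) {
    vb <- vhat
    vb[tau_idx[small]] <- log(TAU_FLOOR)
    free <- setdiff(seq_along(vhat), tau_idx[small])
    fn_b <- function(vf) { vb[free] <- vf; negll(vb) }
    gr_b <- function(vf) { vb[free] <- vf; negll_gr(vb)[free] }
    pol <- try(stats::optim(vb[free], fn_b, gr = gr_b, method = "BFGS",
                            control = list(maxit = config$maxit,
                                           reltol = config$reltol)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$value) &&
        pol$value <= best_value) {
      vb[free] <- pol$par
      vhat <- vb
      best_value <- pol$value
      runs[[best]]$convergence <- pol$convergence
    }
  }
  values[best] <- best_value
  params_hat <- untransform_params(vhat, spec)
  # report taus below 1e-4 as exact zeros
  params_hat$taus[params_hat$taus < 1e-4] <- 0
  loglik <- -values[best]
  gnorm <- sqrt(sum(negll_gr(vhat)^2))
  structure(list(spec = spec,
                 params_hat = params_hat,
                 loglik = loglik,
                 n = n,
                 p = spec$p,
                 bic = compute_bic(loglik, spec$p, n),
                 converged = runs[[best]]$convergence == 0,
                 n_starts = length(starts),
                 best_start_index = best,
                 grad_norm = gnorm,
                 grad_converged = gnorm <= config$grad_tol * (1 + abs(loglik)),
                 optimizer_status = sprintf(
                   "BFGS convergence=%d over %d/%d successful starts",
                   runs[[best]]$convergence, sum(ok), length(starts))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s\n", model_label(x$spec)))
  cat(sprintf("  loglik = %.4f, p = %d, n = %d, BIC = %.4f\n",
              x$loglik, x$p, x$n, x$bic))
  if (x$spec$selection$mechanism != "none") {
    om <- x$params_hat$omega
    cat(sprintf("  omega_hat = %.4f%s\n", om,
                if (om > 1 - 1e-3) " (no detectable selection)" else ""))
  }
  print(x$params_hat)
  invisible(x)
}

#' Bayesian information criterion
#'
#' BIC = p * ln(n) - 2 * loglik, with n the number of effect estimates
#' (the likelihood's units). Lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param p free-parameter count.
#' @param n number of effects.
#' @return Scalar BIC.
#' @export
compute_bic <- function(loglik, p, n) {
  stopifnot(n >= 1)
  p * log(n) - 2 * loglik
}
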