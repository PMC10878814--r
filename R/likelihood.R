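# Observed-data density and log-likelihood for K-component normal-mixture
# random-effects meta-analysis with an optional one-parameter step selection
# function.
#
# Model. Each observed effect y_i is normal around a latent true effect with
# known sampling SD se_i; latent effects follow a K-component normal mixture
# (weights pi_k, means mu_k, heterogeneity SDs tau_k), so marginally
#   y_i ~ sum_k pi_k N(mu_k, tau_k^2 + se_i^2).
# Selective reporting is a step weight function w(y; se): estimates in the
# "selected" region are reported with probability 1, estimates in the
# suppressed region with relative probability omega in (0, 1]. The observed
# density is the weighted marginal renormalized by its expected weight
#   f(y_i) = w(y_i) * mix(y_i) / A_i,   A_i = E[w(Y)] under the mixture.
# The weight acts on the reported estimate (after mixing), not per latent
# component: reporting decisions see the estimate, not component membership.

#' Selection mechanism specification
#'
#' Defines which region of estimate space is "selected" (reported with
#' probability 1) versus suppressed (reported with relative probability
#' omega). Three mechanisms: none; sign (negative estimates suppressed);
#' alpha (non-significant estimates at a given level suppressed, with
#' two-sided or one-sided significance).
#'
#' @param mechanism one of `"none"`, `"sign"`, `"alpha"`.
#' @param alpha_level significance level in (0, 1); required when
#'   `mechanism = "alpha"` (conventional values 0.10 and 0.05).
#' @param sidedness `"two_sided"` (|y|/se exceeds the upper alpha/2 normal
#'   quantile) or `"one_sided"` (y/se exceeds the upper alpha quantile);
#'   only used by the alpha mechanism.
#' @return An object of class `selection_spec`.
#' @seealso [selection_weight()]
#' @export
selection_spec <- function(mechanism = c("none", "sign", "alpha"),
                           alpha_level = NULL,
                           sidedness = c("two_sided", "one_sided")) {
  mechanism <- match.arg(mechanism)
  sidedness <- match.arg(sidedness)
  if (mechanism == "alpha") {
    if (is.null(alpha_level) || !is.numeric(alpha_level) ||
        alpha_level <= 0 || alpha_level >= 1)
      stop_selmix("alpha mechanism requires alpha_level in (0, 1)")
  } else if (!is.null(alpha_level)) {
    stop_selmix("alpha_level is only meaningful for mechanism = 'alpha'")
  }
  structure(list(mechanism = mechanism,
                 alpha_level = if (mechanism == "alpha") alpha_level,
                 sidedness = sidedness),
            class = "selection_spec")
}

#' @rdname selection_spec
#' @export
sel_none <- function() selection_spec("none")

#' @rdname selection_spec
#' @export
sel_sign <- function() selection_spec("sign")

#' @rdname selection_spec
#' @param ... passed to [selection_spec()].
#' @export
sel_alpha <- function(alpha_level, ...)
  selection_spec("alpha", alpha_level = alpha_level, ...)

sel_label <- function(spec) {
  switch(spec$mechanism,
         none = "none",
         sign = "sign",
         alpha = sprintf("alpha%02d", round(100 * spec$alpha_level)))
}

#' Mixture and selection parameters
#'
#' The full parameter vector of one model: mixture weights (a K-simplex),
#' component means and heterogeneity SDs (percentage points), the relative
#' reporting probability omega of a suppressed-region estimate, and optional
#' per-domain mean offsets for the moderated variant. Components are stored
#' in canonical order (means ascending, ties broken by tau then weight) so
#' that label switching cannot make equivalent fits look different.
#'
#' @param weights mixture weights, positive, summing to 1 (length K).
#' @param means component means (length K), percentage points.
#' @param taus component heterogeneity SDs (length K), non-negative.
#' @param omega relative reporting probability in (0, 1]; must be 1 when the
#'   model has no selection component.
#' @param deltas optional named vector of mean offsets for non-reference
#'   domains (moderated variant); the reference domain has offset 0.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(weights, means, taus, omega = 1, deltas = NULL) {
  K <- length(means)
  if (K < 1L || K > 3L) stop_selmix("K must be 1, 2 or 3")
  if (length(weights) != K || length(taus) != K)
    stop_selmix("weights, means and taus must share length K")
  if (any(weights <= 0)) stop_selmix("mixture weights must be positive")
  if (abs(sum(weights) - 1) > 1e-10)
    stop_selmix("mixture weights must sum to 1 (got ", sum(weights), ")")
  if (any(taus < 0)) stop_selmix("taus must be non-negative")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0 || omega > 1)
    stop_selmix("omega must be in (0, 1]")
  ord <- order(means, taus, weights)
  structure(list(K = K,
                 weights = as.numeric(weights[ord]),
                 means = as.numeric(means[ord]),
                 taus = as.numeric(taus[ord]),
                 omega = as.numeric(omega),
                 deltas = deltas),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> K = %d\n", x$K))
  tab <- data.frame(weight = round(x$weights, 4),
                    mean = round(x$means, 4),
                    tau = round(x$taus, 4))
  print(tab, row.names = paste0("  comp", seq_len(x$K)))
  cat(sprintf("  omega = %.4f\n", x$omega))
  if (!is.null(x$deltas)) {
    cat("  domain offsets:\n")
    print(round(x$deltas, 4))
  }
  invisible(x)
}

#' Model specification
#'
#' Identifies one of the model classes fit to an effect-size table: the
#' number of mixture components K, whether and how a selection component is
#' attached, and whether component means are moderated by domain offsets.
#' The free-parameter count p is derived: (3K - 1) mixture parameters
#' (2 when K = 1), plus 1 for omega when selection is on, plus one offset
#' per non-reference domain when moderated.
#'
#' @param K number of mixture components, in {1, 2, 3}.
#' @param selection a [selection_spec()]; default none.
#' @param moderated logical; if `TRUE`, component means receive a common
#'   per-domain offset (reference level: first of `domains`).
#' @param domains character vector of domain levels (required when
#'   `moderated`).
#' @return An object of class `model_spec` with element `p`.
#' @export
model_spec <- function(K, selection = sel_none(), moderated = FALSE,
                       domains = NULL) {
  if (!K %in% 1:3) stop_selmix("K must be 1, 2 or 3")
  stopifnot(inherits(selection, "selection_spec"))
  if (moderated && (is.null(domains) || length(domains) < 2L))
    stop_selmix("moderated models need >= 2 domain levels")
  p <- if (K == 1L) 2L else 3L * K - 1L
  if (selection$mechanism != "none") p <- p + 1L
  if (moderated) p <- p + length(domains) - 1L
  structure(list(K = as.integer(K), selection = selection,
                 moderated = moderated,
                 domains = if (moderated) as.character(domains),
                 p = as.integer(p)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> K = %d, selection = %s%s, p = %d\n",
              x$K, sel_label(x$selection),
              if (x$moderated) ", moderated" else "", x$p))
  invisible(x)
}

model_label <- function(spec) {
  base <- switch(spec$K, "normal", "2-mixture", "3-mixture")
  if (spec$selection$mechanism == "none") {
    if (spec$K == 1L) "normal model" else paste("normal", base)
  } else {
    if (spec$K == 1L) "selection model" else paste("selection", base)
  }
}

check_params_spec <- function(params, spec) {
  if (params$K != spec$K)
    stop_selmix("parameter K (", params$K, ") does not match spec K (",
                spec$K, ")")
  if (spec$selection$mechanism == "none" && params$omega != 1)
    stop_selmix("omega must be 1 when the model has no selection component")
  if (spec$moderated) {
    need <- setdiff(spec$domains, spec$domains[1L])
    if (is.null(params$deltas) || !setequal(names(params$deltas), need))
      stop_selmix("moderated spec needs deltas named for domains: ",
                  paste(need, collapse = ", "))
  }
  invisible(TRUE)
}

#' Step selection weight of an observed estimate
#'
#' The relative reporting probability of an estimate `y` with standard
#' error `se`: 1 in the selected region, `omega` in the suppressed region.
#' Mechanism `"none"` returns 1 everywhere; `"sign"` selects y > 0;
#' `"alpha"` selects statistically significant estimates (two-sided:
#' |y|/se above the 1 - alpha/2 normal quantile; one-sided: y/se above the
#' 1 - alpha quantile).
#'
#' @param y numeric vector of effect estimates.
#' @param se numeric vector of standard errors (recycled against `y`).
#' @param spec a [selection_spec()].
#' @param omega relative reporting probability in (0, 1].
#' @return Numeric vector of weights in (0, 1].
#' @export
selection_weight <- function(y, se, spec, omega) {
  stopifnot(inherits(spec, "selection_spec"))
  if (omega <= 0 && spec$mechanism != "none") {
    # omega = 0 only arises as a limit in generators/tests
    if (omega < 0) stop_selmix("omega must be non-negative")
  }
  w <- rep(1, length(y))
  w[!selected_region(y, se, spec)] <- omega
  w
}

# Indicator of the selected (fully reported) region.
selected_region <- function(y, se, spec) {
  switch(spec$mechanism,
         none = rep(TRUE, length(y)),
         sign = y > 0,
         alpha = {
           if (spec$sidedness == "two_sided")
             abs(y) / se > stats::qnorm(1 - spec$alpha_level / 2)
           else
             y / se > stats::qnorm(1 - spec$alpha_level)
         })
}

#' Marginal SD of an observed effect within one component
#'
#' The sampling SD and the component heterogeneity combine as
#' sqrt(tau^2 + se^2); tau = 0 is admissible (fixed-effect spike).
#'
#' @param tau non-negative heterogeneity SD.
#' @param se positive sampling standard error.
#' @return sqrt(tau^2 + se^2).
#' @export
component_marginal_sd <- function(tau, se) sqrt(tau^2 + se^2)

# P(Y in selected region) for one component with mean m and marginal SD s,
# vectorized over records. `se` enters the alpha cutpoints.
prob_selected <- function(m, s, se, spec) {
  switch(spec$mechanism,
         none = rep(1, length(s)),
         sign = stats::pnorm(m / s),
         alpha = {
           if (spec$sidedness == "two_sided") {
             cut <- stats::qnorm(1 - spec$alpha_level / 2) * se
             stats::pnorm((-cut - m) / s) + stats::pnorm((m - cut) / s)
           } else {
             cut <- stats::qnorm(1 - spec$alpha_level) * se
             stats::pnorm((m - cut) / s)
           }
         })
}

# Component means per record: mu_k plus the record's domain offset when the
# model is moderated. Returns an n x K matrix.
record_component_means <- function(n, params, domain = NULL) {
  mu <- matrix(params$means, nrow = n, ncol = params$K, byrow = TRUE)
  if (!is.null(params$deltas) && !is.null(domain)) {
    off <- rep(0, n)
    hit <- domain %in% names(params$deltas)
    off[hit] <- params$deltas[domain[hit]]
    mu <- mu + off
  }
  mu
}

#' Expected selection weight (normalizing constant)
#'
#' The expected reporting weight A_i = sum_k pi_k * [P_k(selected) +
#' omega * (1 - P_k(selected))] under the marginal mixture of record i,
#' which renormalizes the weighted density. Equals 1 exactly when the
#' mechanism is none or omega = 1.
#'
#' @param se numeric vector of standard errors.
#' @param params a [mixture_params()].
#' @param spec a [selection_spec()].
#' @param domain optional domain labels (moderated variant).
#' @return Numeric vector in (0, 1], one value per `se`.
#' @export
normalizing_constant <- function(se, params, spec, domain = NULL) {
  stopifnot(inherits(params, "mixture_params"),
            inherits(spec, "selection_spec"))
  n <- length(se)
  if (spec$mechanism == "none" || params$omega == 1) return(rep(1, n))
  s <- sqrt(outer(se^2, params$taus^2, `+`))     # n x K marginal SDs
  mu <- record_component_means(n, params, domain)
  P <- matrix(0, n, params$K)
  for (k in seq_len(params$K))
    P[, k] <- prob_selected(mu[, k], s[, k], se, spec)
  A_k <- P + params$omega * (1 - P)
  as.numeric(A_k %*% params$weights)
}

#' Observed-data density under selection
#'
#' Density of a reported estimate: the step weight times the marginal
#' mixture density, renormalized by the expected weight
#' ([normalizing_constant()]). With mechanism `"none"` this reduces to the
#' plain mixture marginal. Integrates to 1 in y for every se.
#'
#' @param y numeric vector of effect estimates.
#' @param se numeric vector of standard errors (recycled against `y`).
#' @param params a [mixture_params()].
#' @param spec a [selection_spec()].
#' @param domain optional domain labels (moderated variant).
#' @param log logical; return the log density.
#' @return Numeric vector of (log) density values.
#' @export
observed_density <- function(y, se, params, spec, domain = NULL,
                             log = FALSE) {
  stopifnot(inherits(params, "mixture_params"),
            inherits(spec, "selection_spec"))
  n <- max(length(y), length(se))
  y <- rep_len(y, n); se <- rep_len(se, n)
  if (!is.null(domain)) domain <- rep_len(domain, n)
  s <- sqrt(outer(se^2, params$taus^2, `+`))
  mu <- record_component_means(n, params, domain)
  lcomp <- matrix(0, n, params$K)
  for (k in seq_len(params$K))
    lcomp[, k] <- log(params$weights[k]) +
      stats::dnorm(y, mean = mu[, k], sd = s[, k], log = TRUE)
  lmix <- if (params$K == 1L) lcomp[, 1L] else row_logsumexp(lcomp)
  if (spec$mechanism == "none" || params$omega == 1) {
    lf <- lmix
  } else {
    w <- selection_weight(y, se, spec, params$omega)
    lA <- log(normalizing_constant(se, params, spec, domain))
    lf <- log(w) + lmix - lA
  }
  if (log) lf else exp(lf)
}

#' Log-likelihood of a model on an effect-size dataset
#'
#' Sum over records of the log observed-data density, treating effects as
#' independent (the unit of analysis is the effect estimate; trial labels
#' are kept for extensions but do not enter the likelihood). Computed with
#' log-sum-exp stabilization; returns -Inf (not an error) if any record has
#' zero density.
#'
#' @param dataset an [effect_dataset()].
#' @param spec a [model_spec()].
#' @param params a [mixture_params()] dimensionally consistent with `spec`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, spec, params) {
  stopifnot(inherits(dataset, "effect_dataset"),
            inherits(spec, "model_spec"))
  check_params_spec(params, spec)
  lf <- observed_density(dataset$effect, dataset$se, params,
                         spec$selection,
                         domain = if (spec$moderated) dataset$domain,
                         log = TRUE)
  if (any(is.nan(lf))) return(-Inf)
  sum(lf)
}
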