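# BIC weights, BIC-based Bayesian model averaging over selection
# mechanisms, and the model-class comparison table.

#' Schwarz (BIC) weights
#'
#' w_m = exp(-0.5 * (BIC_m - min BIC)) / sum_j exp(-0.5 * (BIC_j - min
#' BIC)); an approximate posterior model probability under equal priors.
#' Invariant to adding a constant to all BICs; infinite BICs get weight 0.
#'
#' @param bics numeric vector of BIC values (at least one finite).
#' @return Simplex vector of the same length.
#' @export
bic_weights <- function(bics) {
  if (!any(is.finite(bics))) stop_selmix("all BIC values are infinite")
  l <- -0.5 * bics
  w <- exp(l - logsumexp(l))
  w / sum(w)
}

#' Average the three selection mechanisms into one model class
#'
#' Combines the same-K selection fits (sign, alpha = 0.10, alpha = 0.05)
#' with equal prior mass 1/3 each: class evidence
#' E = (1/3) * sum_t exp(-BIC_t / 2), represented as a class pseudo-BIC
#' -2 * ln E, plus within-class mechanism weights. Computed via
#' log-sum-exp, so it is shift-invariant and safe for large BICs.
#'
#' @param fits list of three `fit_result`s with identical K and distinct
#'   selection mechanisms.
#' @return List with `pseudo_bic`, `within_weights` (named by mechanism),
#'   `K`, and the input `fits`.
#' @export
average_selection_types <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  Ks <- vapply(fits, function(f) f$spec$K, integer(1))
  if (length(unique(Ks)) != 1L)
    stop_selmix("selection fits must share K (got ",
                paste(Ks, collapse = ", "), ")")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  l <- -0.5 * bics
  lse <- logsumexp(l)
  pseudo_bic <- -2 * (lse - log(length(fits)))
  within <- exp(l - lse)
  names(within) <- vapply(fits, function(f) sel_label(f$spec$selection),
                          character(1))
  list(pseudo_bic = pseudo_bic, within_weights = within / sum(within),
       K = Ks[1L], fits = fits)
}

default_mechanisms <- function(sidedness = "two_sided") {
  list(sel_sign(),
       sel_alpha(0.10, sidedness = sidedness),
       sel_alpha(0.05, sidedness = sidedness))
}

#' Compare the normal and selection model classes
#'
#' Fits, for each K up to `K_max`, the plain mixture model and the three
#' selection-mechanism models, collapses each K's selection fits into one
#' class via [average_selection_types()], and returns BIC weights over the
#' 2 * K_max model classes. With `K_max = 2` the table has 4 entries
#' (normal model, normal 2-mixture, selection model, selection 2-mixture);
#' with `K_max = 3`, 6 entries.
#'
#' @param dataset an [effect_dataset()].
#' @param K_max 2 or 3.
#' @param config a [fit_config()].
#' @param sidedness significance sidedness for the alpha mechanisms.
#' @param class_weight_method `"pseudo_bic"` (default): class weights from
#'   the averaged classes' representative BICs (equal prior mass per class,
#'   split 1/3 per mechanism inside a selection class); `"sum_within"`:
#'   BIC weights computed over the full per-model table (equal prior mass
#'   per individual model), then summed within each selection class. The
#'   conventions differ only in how prior mass is allocated and typically
#'   agree to the displayed precision when one mechanism dominates.
#' @return An object of class `comparison_table`: data frame `table` with
#'   columns `class`, `K`, `selection`, `bic`, `weight`; list `fits` of all
#'   underlying fits; list `selection_averages` per K; `method`.
#' @export
compare_model_classes <- function(dataset, K_max = 2L,
                                  config = fit_config(),
                                  sidedness = "two_sided",
                                  class_weight_method = c("pseudo_bic",
                                                          "sum_within")) {
  stopifnot(K_max %in% 2:3)
  class_weight_method <- match.arg(class_weight_method)
  mechanisms <- default_mechanisms(sidedness)
  fits <- list()
  sel_avg <- list()
  rows <- list()
  prev_none <- NULL
  for (K in seq_len(K_max)) {
    spec0 <- model_spec(K)
    # warm-start the K-mixture from the (K-1)-mixture optimum with a split
    # component, which also protects the loglik nesting across K
    warm0 <- if (!is.null(prev_none))
      list(split_component(prev_none$params_hat))
    f0 <- fit_with_context(dataset, spec0, config, extra_starts = warm0)
    prev_none <- f0
    fits[[model_label(spec0)]] <- f0
    rows[[length(rows) + 1L]] <-
      data.frame(class = model_label(spec0), K = K, selection = "none",
                 bic = f0$bic, stringsAsFactors = FALSE)
    # warm-start each selection fit from the no-selection optimum with
    # omega essentially at the nested boundary (so the selection class can
    # never score below its nested no-selection model) and at 0.5
    warm_sel <- lapply(c(1 - 1e-9, 0.5), function(om) {
      p <- f0$params_hat
      mixture_params(p$weights, p$means, pmax(p$taus, 1e-6), omega = om,
                     deltas = p$deltas)
    })
    sel_fits <- lapply(mechanisms, function(m) {
      sp <- model_spec(K, selection = m)
      f <- fit_with_context(dataset, sp, config, extra_starts = warm_sel)
      fits[[paste(model_label(sp), sel_label(m))]] <<- f
      f
    })
    avg <- average_selection_types(sel_fits)
    sel_avg[[paste0("K", K)]] <- avg
    lab <- model_label(model_spec(K, selection = sel_sign()))
    rows[[length(rows) + 1L]] <-
      data.frame(class = lab, K = K, selection = "averaged",
                 bic = avg$pseudo_bic, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  # canonical presentation order: all normal classes, then all selection
  tab <- tab[order(tab$selection != "none", tab$K), ]
  if (class_weight_method == "pseudo_bic") {
    tab$weight <- bic_weights(tab$bic)
  } else {
    # full per-model table, equal prior mass per individual model
    all_bics <- c()
    grp <- c()
    for (K in seq_len(K_max)) {
      all_bics <- c(all_bics, tab$bic[tab$selection == "none" &
                                        tab$K == K][1L])
      grp <- c(grp, paste0("none", K))
    }
    for (K in seq_len(K_max)) {
      bt <- vapply(sel_avg[[paste0("K", K)]]$fits, `[[`, numeric(1), "bic")
      all_bics <- c(all_bics, bt)
      grp <- c(grp, rep(paste0("sel", K), length(bt)))
    }
    w_full <- bic_weights(all_bics)
    w_class <- vapply(split(w_full, grp), sum, numeric(1))
    key <- ifelse(tab$selection == "none", paste0("none", tab$K),
                  paste0("sel", tab$K))
    tab$weight <- unname(w_class[key])
  }
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, selection_averages = sel_avg,
                 method = class_weight_method),
            class = "comparison_table")
}

# Duplicate the widest-weight component of a K-params into K+1 components
# (small mean offset, weights split in half): a nested-model warm start.
split_component <- function(params) {
  j <- which.max(params$weights)
  eps <- 0.25 * max(params$taus[j], 0.5)
  w <- params$weights; m <- params$means; t <- params$taus
  w_new <- c(w[-j], w[j] / 2, w[j] / 2)
  m_new <- c(m[-j], m[j] - eps, m[j] + eps)
  t_new <- c(t[-j], t[j], t[j])
  mixture_params(w_new, m_new, pmax(t_new, 1e-6), omega = params$omega,
                 deltas = params$deltas)
}

# fit_model with the failing model class named in any error.
fit_with_context <- function(dataset, spec, config, extra_starts = list()) {
  tryCatch(fit_model(dataset, spec, config, extra_starts = extra_starts),
           error = function(e)
             stop_selmix("fit failed for class '", model_label(spec),
                         " (", sel_label(spec$selection), ")': ",
                         conditionMessage(e)))
}

#' @export
print.comparison_table <- function(x, ...) {
  tab <- x$table
  tab$bic <- round(tab$bic, 2)
  tab$weight <- sprintf("%.3f", tab$weight)
  cat("<comparison_table> BIC weights over model classes\n")
  print(tab, row.names = FALSE)
  for (nm in names(x$selection_averages)) {
    w <- x$selection_averages[[nm]]$within_weights
    cat(sprintf("  %s within-selection weights: %s\n", nm,
                paste(sprintf("%s=%.3f", names(w), w), collapse = ", ")))
  }
  invisible(x)
}

#' Rank selection mechanisms by BIC
#'
#' Reports, overall and per K, which selection mechanism attains the lowest
#' BIC; exact ties are reported as ties.
#'
#' @param fits list of selection-model `fit_result`s (any mix of K).
#' @return List with `overall` (mechanism label(s) of the lowest-BIC fit),
#'   `per_K` (named list of mechanism label(s) per K) and a ranking data
#'   frame `ranking`.
#' @export
preferred_selection_mechanism <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  is_sel <- vapply(fits, function(f) f$spec$selection$mechanism != "none",
                   logical(1))
  fits <- fits[is_sel]
  if (length(fits) == 0L) stop_selmix("no selection fits supplied")
  df <- data.frame(
    K = vapply(fits, function(f) f$spec$K, integer(1)),
    mechanism = vapply(fits, function(f) sel_label(f$spec$selection),
                       character(1)),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    stringsAsFactors = FALSE)
  df <- df[order(df$bic), ]
  rownames(df) <- NULL
  best <- function(d) d$mechanism[d$bic == min(d$bic)]
  list(overall = best(df),
       per_K = lapply(split(df, df$K), best),
       ranking = df)
}
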