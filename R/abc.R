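#' Simulate a reference table of parameter draws and summary statistics
#'
#' Draws `n_sims` parameter vectors from the model's priors and simulates the
#' model's summary statistics for each.
#'
#' @param model an `mt_demographic_model`.
#' @param n_sims number of simulations.
#' @param mut_model mutation model.
#' @param params optional fixed parameter vector; when supplied, all
#'   simulations run at these values (used for final goodness-of-fit runs).
#' @param fst_mode fixation-index distance mode, see [simulate_dataset()].
#' @return a list with `params` (tibble, one row per draw) and `stats`
#'   (numeric matrix, one row per draw).
#' @export
simulate_reference <- function(model, n_sims, mut_model = mutation_model(),
                               params = NULL,
                               fst_mode = c("pairwise_diff",
                                            "haplotype_freq")) {
  fst_mode <- match.arg(fst_mode)
  n_sims <- stopifnot_scalar_count(n_sims, "n_sims")
  tips <- compile_model_tips(model)
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  root_seq <- unname(base_code[rcrs_window()])
  cat_rates <- discrete_gamma_rates(mut_model$gamma_shape,
                                    mut_model$n_categories)
  stat_names <- names(model$observed)
  k <- length(model$priors)
  pmat <- matrix(NA_real_, n_sims, k,
                 dimnames = list(NULL, names(model$priors)))
  smat <- matrix(NA_real_, n_sims, length(stat_names),
                 dimnames = list(NULL, stat_names))
  groups <- model$groups
  pairs <- model$fst_pairs
  for (i in seq_len(n_sims)) {
    p <- if (is.null(params)) draw_model_params(model) else params
    inst <- instantiate_model(model, p)
    res <- simulate_hap_ids(tips$tip_age, tips$tip_deme0, inst$deme, inst$ev,
                            mut_model, root_seq, cat_rates)
    pmat[i, ] <- p
    smat[i, ] <- summary_stats_from_ids(res$hap_id, tips$tip_group, groups,
                                        pairs, hap_seq = res$hap_seq,
                                        fst_mode = fst_mode)
  }
  list(params = tibble::as_tibble(pmat), stats = smat)
}

#' ABC rejection step
#'
#' Standardises every summary statistic by its standard deviation across the
#' simulated pool (statistics on different scales -- diversities versus
#' fixation indices -- would otherwise dominate each other), computes the
#' Euclidean distance of each simulation to the observed vector, and retains
#' the `fraction` of simulations with the smallest distances. The recorded
#' tolerance is the largest retained distance.
#'
#' @param observed named observed statistic vector.
#' @param sims reference table from [simulate_reference()] (or a list with
#'   `params` and `stats` of matching names).
#' @param fraction fraction of simulations to retain.
#' @return an object of class `mt_abc_rejection`: `retained` (tibble of
#'   parameter draws with their distances), `tolerance`, `stat_sd`,
#'   `n_sims`, `fraction`, `observed`.
#' @export
abc_reject <- function(observed, sims, fraction = 0.01) {
  stats <- sims$stats
  if (nrow(stats) < 100) abort("need at least 100 simulations.")
  if (!all(names(observed) %in% colnames(stats))) {
    abort("observed and simulated statistic names do not match.")
  }
  stats <- stats[, names(observed), drop = FALSE]
  sds <- apply(stats, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warn(sprintf("dropping zero-variance statistic(s): %s",
                 paste(names(observed)[drop], collapse = ", ")))
    observed <- observed[!drop]
    stats <- stats[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (!length(observed)) abort("no informative statistics left.")
  z <- sweep(stats, 2, sds, "/")
  zo <- observed / sds
  dist <- sqrt(rowSums(sweep(z, 2, zo)^2))
  m <- ceiling(fraction * nrow(stats))
  idx <- order(dist)[seq_len(m)]
  retained <- tibble::as_tibble(sims$params[idx, , drop = FALSE])
  retained$distance <- dist[idx]
  structure(list(retained = retained, tolerance = max(dist[idx]),
                 stat_sd = sds, n_sims = nrow(stats), fraction = fraction,
                 observed = observed),
            class = "mt_abc_rejection")
}

#' @export
print.mt_abc_rejection <- function(x, ...) {
  cat(sprintf(
    "<mt_abc_rejection> %d of %d simulations retained (tolerance %.3f)\n",
    nrow(x$retained), x$n_sims, x$tolerance))
  invisible(x)
}

#' Posterior point estimates from retained draws
#'
#' Per-parameter point estimate over the retained posterior sample: the
#' posterior median (default) or the mode of a kernel density estimate.
#' Estimates always lie inside the prior support.
#'
#' @param rejection an `mt_abc_rejection` (or a data frame of retained
#'   draws).
#' @param method `"median"` or `"mode"`.
#' @return a named numeric vector.
#' @export
estimate_posterior <- function(rejection, method = c("median", "mode")) {
  method <- match.arg(method)
  draws <- if (inherits(rejection, "mt_abc_rejection")) {
    rejection$retained
  } else {
    rejection
  }
  draws <- draws[setdiff(names(draws), "distance")]
  if (!nrow(draws)) abort("no retained draws.")
  vapply(draws, function(x) {
    if (method == "median" || length(unique(x)) < 5) {
      stats::median(x)
    } else {
      d <- stats::density(x, from = min(x), to = max(x))
      d$x[which.max(d$y)]
    }
  }, numeric(1))
}

#' Goodness of fit of a fitted model: simulation-based AIC
#'
#' Re-simulates the model `n_final` times at the posterior point estimates
#' and estimates the model likelihood as the fraction of these final
#' simulations whose (stage-1-standardised) distance to the observed vector
#' falls within the stage-1 tolerance, floored at `1/(n_final + 1)` to avoid
#' a zero. `AIC = -2 log L + 2k` with `k` the model's free-parameter count.
#'
#' @param model an `mt_demographic_model`.
#' @param point named posterior point estimates.
#' @param rejection the stage-1 `mt_abc_rejection` (supplies tolerance and
#'   standardisation).
#' @param n_final number of final simulations (>= 100).
#' @param mut_model mutation model.
#' @param fst_mode fixation-index distance mode, see [simulate_dataset()].
#' @return a list with `aic`, `likelihood`, `frac_within`, `n_final`.
#' @export
model_fit <- function(model, point, rejection, n_final = 10000,
                      mut_model = mutation_model(),
                      fst_mode = c("pairwise_diff", "haplotype_freq")) {
  fst_mode <- match.arg(fst_mode)
  n_final <- stopifnot_scalar_count(n_final, "n_final")
  if (n_final < 100) abort("`n_final` must be at least 100.")
  final <- simulate_reference(model, n_final, mut_model = mut_model,
                              params = point[names(model$priors)],
                              fst_mode = fst_mode)
  obs <- rejection$observed
  sds <- rejection$stat_sd
  z <- sweep(final$stats[, names(obs), drop = FALSE], 2, sds, "/")
  dist <- sqrt(rowSums(sweep(z, 2, obs / sds)^2))
  frac <- mean(dist <= rejection$tolerance)
  lik <- max(frac, 1 / (n_final + 1))
  list(aic = -2 * log(lik) + 2 * model$k, likelihood = lik,
       frac_within = frac, n_final = n_final)
}

#' Akaike weights
#'
#' Relative model likelihoods `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)` with
#' `D_i = AIC_i - min(AIC)`; invariant under adding a constant to all AICs
#' and summing to one.
#'
#' @param aics numeric vector of AIC values (length >= 1).
#' @return numeric vector of weights, preserving names.
#' @examples
#' akaike_weights(c(m1 = 10, m2 = 12))
#' @export
akaike_weights <- function(aics) {
  if (!length(aics)) abort("no AIC values supplied.")
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Run the full ABC model comparison
#'
#' For each model: simulate `n_sims` prior draws, retain the closest
#' `fraction` (rejection step), take posterior point estimates, re-simulate
#' `n_final` datasets at those estimates, convert the within-tolerance
#' fraction into an AIC, and finally convert AICs into Akaike weights across
#' models. Deterministic given `seed`.
#'
#' @param models a list of `mt_demographic_model` objects (e.g. a subset of
#'   [preset_models()]).
#' @param n_sims prior simulations per model.
#' @param fraction rejection fraction.
#' @param n_final final simulations per model.
#' @param seed integer seed (applied locally once for the whole comparison).
#' @param observed optional named list of observed vectors, overriding each
#'   model's fixture-derived observed statistics (used with pseudo-observed
#'   data); a single named vector is recycled by name matching.
#' @param point_method posterior point estimator, `"median"` or `"mode"`.
#' @param mut_model mutation model.
#' @param fst_mode fixation-index distance mode, see [simulate_dataset()].
#' @return an `mt_abc` tibble, one row per model, ranked by Akaike weight:
#'   columns `model`, `k`, `n_sims`, `tolerance`, `likelihood`, `aic`,
#'   `akaike_weight`, plus list-columns `posterior` (point estimates) and
#'   `retained` (posterior draws).
#' @export
run_model_comparison <- function(models, n_sims = 20000, fraction = 0.01,
                                 n_final = 10000, seed = NULL,
                                 observed = NULL,
                                 point_method = c("median", "mode"),
                                 mut_model = mutation_model(),
                                 fst_mode = c("pairwise_diff",
                                              "haplotype_freq")) {
  point_method <- match.arg(point_method)
  fst_mode <- match.arg(fst_mode)
  if (inherits(models, "mt_demographic_model")) models <- list(models)
  names(models) <- vapply(models, `[[`, character(1), "name")
  rows <- with_seed(seed, lapply(models, function(model) {
    obs <- model$observed
    if (!is.null(observed)) {
      src <- if (is.list(observed)) observed[[model$name]] %||%
        observed[[1]] else observed
      obs[names(obs)] <- src[names(obs)]
      if (anyNA(obs)) {
        abort(sprintf("observed override lacks statistic(s) for model %s",
                      model$name))
      }
    }
    model$observed <- obs
    ref <- simulate_reference(model, n_sims, mut_model = mut_model,
                              fst_mode = fst_mode)
    rej <- abc_reject(obs, ref, fraction = fraction)
    post <- estimate_posterior(rej, method = point_method)
    fit <- model_fit(model, post, rej, n_final = n_final,
                     mut_model = mut_model, fst_mode = fst_mode)
    tibble::tibble(
      model = .env$model$name, k = .env$model$k, n_sims = n_sims,
      n_final = n_final, tolerance = rej$tolerance,
      likelihood = fit$likelihood, frac_within = fit$frac_within,
      aic = fit$aic, posterior = list(post), retained = list(rej$retained)
    )
  }))
  out <- dplyr::bind_rows(rows)
  out$akaike_weight <- akaike_weights(out$aic)
  out <- out[order(-out$akaike_weight), ]
  class(out) <- c("mt_abc", class(out))
  out
}

#' @export
tidy.mt_abc <- function(x, ...) {
  purrr::map2_dfr(x$model, x$posterior, function(m, p) {
    tibble::tibble(model = m, parameter = names(p), estimate = unname(p))
  })
}

#' @export
glance.mt_abc <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    best_model = x$model[1],
    best_weight = x$akaike_weight[1],
    delta_aic = if (nrow(x) > 1) x$aic[2] - x$aic[1] else NA_real_
  )
}

#' @export
autoplot.mt_abc <- function(object, ...) {
  d <- tibble::tibble(model = factor(object$model, levels = rev(object$model)),
                      weight = object$akaike_weight)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
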