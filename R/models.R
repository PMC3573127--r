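# canonical population ordering used to name F_ST statistics
POP_ORDER <- c("NEE", "saa", "CE", "aHG", "aUzPo", "aBOO", "aPWC")

ANCHOR_NE <- 5000      # Palaeolithic ancestral haploid size
ANCHOR_TIME <- 1500    # generations ago

# sampling schedules (group label, deme, ages, sizes) for the populations in
# the observed-statistics fixture; aHG tips are spread evenly over the
# reported age range
sample_schedule <- function(group, deme, observed) {
  p <- observed$populations
  row <- p[p$label == group, ]
  if (!nrow(row)) abort(sprintf("population '%s' not in observed fixture", group))
  if (is.na(row$age_generations) && row$age_min < row$age_max) {
    tibble::tibble(deme = deme,
                   age = seq(row$age_min, row$age_max, length.out = row$n),
                   n = 1L, group = group)
  } else {
    tibble::tibble(deme = deme, age = row$age_generations, n = row$n,
                   group = group)
  }
}

#' Preset demographic models
#'
#' The compared demographic hypotheses. Continuity models `H0a`-`H0e` place
#' all samples in a single exponentially growing deme whose size is anchored
#' at the Palaeolithic ancestral size of 5,000 (haploid) 1,500 generations
#' ago, with the present-day size drawn from a uniform prior
#' (1e5-3e7 for NEE-terminated models, 1e3-5e5 for the Saami model):
#' * `H0a` - continuity NEE + aUzPo; `H0b` - NEE + aBOO; `H0c` - Saami +
#'   aUzPo; `H0d` - NEE + aHG + aPWC + aUzPo; `H0e` - NEE + aHG + aPWC +
#'   aBOO.
#'
#' Migration models `H1_*` have a sink deme (NEE, carrying the ancient
#' sample) and a source deme (CE), both growing, with a divergence time
#' uniform on 620-2,600 generations, a single migration pulse from CE into
#' NEE at a time uniform on 2-139 generations, a fixed migrant fraction (10,
#' 50 or 75 percent), and both present-day sizes uniform on 1e5-1.5e7:
#' `H1_uzpo_10/50/75` and `H1_boo_10/50/75`.
#'
#' Free-parameter counts are k = 1 (H0) and k = 4 (H1; the migrant fraction
#' is fixed per variant). Each model's observed statistics are all applicable
#' fixture entries (diversities and pairwise fixation indices among its
#' sampled populations; pairs without a reported value are excluded).
#'
#' @param observed observed-statistics fixture, see [load_observed_stats()].
#' @return a named list of `mt_demographic_model` objects.
#' @export
preset_models <- function(observed = load_observed_stats()) {
  h0 <- function(name, modern, ancients, prior) {
    samples <- dplyr::bind_rows(
      sample_schedule(modern, modern, observed),
      lapply(ancients, sample_schedule, deme = modern, observed = observed)
    )
    new_model(name, type = "H0", deme_labels = modern,
              priors = list(ne = prior), k = 1L, samples = samples,
              observed = observed)
  }
  h1 <- function(name, ancient, fraction) {
    samples <- dplyr::bind_rows(
      sample_schedule("NEE", "NEE", observed),
      sample_schedule("CE", "CE", observed),
      sample_schedule(ancient, "NEE", observed)
    )
    new_model(name, type = "H1", deme_labels = c("NEE", "CE"),
              priors = list(ne_sink = c(1e5, 1.5e7),
                            ne_source = c(1e5, 1.5e7),
                            t_migration = c(2, 139),
                            t_divergence = c(620, 2600)),
              k = 4L, samples = samples, observed = observed,
              migrant_fraction = fraction)
  }
  models <- list(
    H0a = h0("H0a", "NEE", "aUzPo", c(1e5, 3e7)),
    H0b = h0("H0b", "NEE", "aBOO", c(1e5, 3e7)),
    H0c = h0("H0c", "saa", "aUzPo", c(1e3, 5e5)),
    H0d = h0("H0d", "NEE", c("aHG", "aPWC", "aUzPo"), c(1e5, 3e7)),
    H0e = h0("H0e", "NEE", c("aHG", "aPWC", "aBOO"), c(1e5, 3e7)),
    H1_uzpo_10 = h1("H1_uzpo_10", "aUzPo", 0.10),
    H1_uzpo_50 = h1("H1_uzpo_50", "aUzPo", 0.50),
    H1_uzpo_75 = h1("H1_uzpo_75", "aUzPo", 0.75),
    H1_boo_10 = h1("H1_boo_10", "aBOO", 0.10),
    H1_boo_50 = h1("H1_boo_50", "aBOO", 0.50),
    H1_boo_75 = h1("H1_boo_75", "aBOO", 0.75)
  )
  models
}

#' Build a custom demographic model
#'
#' Lower-level constructor behind [preset_models()], for bespoke model
#' structures -- e.g. a continuity model that also samples the CE group from
#' the same deme, used as the generating model in recovery experiments. H0
#' models have one deme (prior on `ne`); H1 models have a sink and a source
#' deme (priors on `ne_sink`, `ne_source`, `t_migration`, `t_divergence` and
#' a fixed `migrant_fraction`).
#'
#' @param name model name.
#' @param type `"H0"` or `"H1"`.
#' @param deme_labels one label (H0) or `c(sink, source)` (H1).
#' @param priors named list of `c(lower, upper)` uniform prior bounds.
#' @param k free-parameter count entering the AIC penalty.
#' @param samples sampling schedule tibble with columns `deme`, `age`, `n`,
#'   `group`.
#' @param observed observed-statistics fixture ([load_observed_stats()]);
#'   groups must appear in its population table.
#' @param migrant_fraction fixed migrant fraction for H1 models.
#' @return an `mt_demographic_model`.
#' @export
demographic_model <- function(name, type, deme_labels, priors, k, samples,
                              observed = load_observed_stats(),
                              migrant_fraction = NULL) {
  type <- match.arg(type, c("H0", "H1"))
  if (type == "H1" && is.null(migrant_fraction)) {
    abort("H1 models need a `migrant_fraction`.")
  }
  new_model(name, type, deme_labels, priors, as.integer(k), samples,
            observed, migrant_fraction)
}

new_model <- function(name, type, deme_labels, priors, k, samples, observed,
                      migrant_fraction = NULL) {
  for (p in priors) {
    if (length(p) != 2 || !(p[1] < p[2])) abort("malformed prior bounds.")
  }
  if (any(samples$age >= ANCHOR_TIME)) {
    abort("sampling ages must predate the ancestral anchor.")
  }
  groups <- unique(samples$group)
  # applicable observed statistics: h for every sampled group, fst for every
  # pair with a reported value
  obs_h <- stats::setNames(
    observed$populations$haplotype_diversity[
      match(groups, observed$populations$label)],
    paste0("h_", groups))
  pairs <- t(utils::combn(groups, 2))
  # order pairs canonically so names match the fixture convention
  swap <- match(pairs[, 1], POP_ORDER) > match(pairs[, 2], POP_ORDER)
  pairs[swap, ] <- pairs[swap, 2:1]
  fkey <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  okey <- paste(pmin(observed$fst$pop_a, observed$fst$pop_b),
                pmax(observed$fst$pop_a, observed$fst$pop_b))
  fst_val <- observed$fst$fst[match(fkey, okey)]
  keep <- !is.na(fst_val)
  pairs <- pairs[keep, , drop = FALSE]
  obs_fst <- stats::setNames(fst_val[keep],
                             paste0("fst_", pairs[, 1], "_", pairs[, 2]))
  structure(list(
    name = name, type = type, deme_labels = deme_labels, priors = priors,
    k = k, samples = samples, groups = groups, fst_pairs = pairs,
    observed = c(obs_h, obs_fst),
    migrant_fraction = migrant_fraction
  ), class = "mt_demographic_model")
}

#' @export
print.mt_demographic_model <- function(x, ...) {
  cat(sprintf("<mt_demographic_model> %s (%s, k = %d)\n", x$name, x$type, x$k))
  cat("  demes:", paste(x$deme_labels, collapse = ", "), "\n")
  cat("  samples:", paste(sprintf("%s (n=%d)", x$groups,
                                  vapply(split(x$samples$n, x$samples$group)[x$groups],
                                         sum, numeric(1))),
                          collapse = ", "), "\n")
  cat("  statistics:", paste(names(x$observed), collapse = ", "), "\n")
  invisible(x)
}

#' Draw one parameter vector from a model's priors
#'
#' All priors are uniform on their stated bounds (present-day effective
#' sizes on the natural scale; event times in generations).
#'
#' @param model an `mt_demographic_model`.
#' @return a named numeric vector.
#' @export
draw_model_params <- function(model) {
  vapply(model$priors, function(p) stats::runif(1, p[1], p[2]), numeric(1))
}

# deme/event vectors for one concrete parameter draw, in the form consumed by
# the C++ simulator
instantiate_model <- function(model, params) {
  if (model$type == "H0") {
    ne0 <- unname(params[["ne"]])
    list(deme = list(ne0 = ne0,
                     growth = log(ne0 / ANCHOR_NE) / ANCHOR_TIME,
                     anchor = ANCHOR_TIME),
         ev = list(time = numeric(0), type = integer(0), from = integer(0),
                   to = integer(0), prob = numeric(0)))
  } else {
    ne0 <- c(unname(params[["ne_sink"]]), unname(params[["ne_source"]]))
    list(deme = list(ne0 = ne0,
                     growth = log(ne0 / ANCHOR_NE) / ANCHOR_TIME,
                     anchor = c(ANCHOR_TIME, ANCHOR_TIME)),
         # backward in time: pulse moves sink (NEE, deme 0) lineages into the
         # source (CE, deme 1); at divergence CE merges into NEE
         ev = list(time = c(params[["t_migration"]], params[["t_divergence"]]),
                   type = c(0L, 1L), from = c(0L, 1L), to = c(1L, 0L),
                   prob = c(model$migrant_fraction, 1)))
  }
}

# static per-model tip layout used by the simulation loops
compile_model_tips <- function(model) {
  tip_age <- rep(model$samples$age, model$samples$n)
  tip_deme0 <- rep(match(model$samples$deme, model$deme_labels) - 1L,
                   model$samples$n)
  tip_group <- rep(model$samples$group, model$samples$n)
  list(tip_age = tip_age, tip_deme0 = tip_deme0, tip_group = tip_group)
}

#' Simulate the summary statistics of one model draw
#'
#' Draws a genealogy and mutations under `model` at the given parameter
#' values and returns the model's summary-statistic vector (the same named
#' statistics its observed vector carries).
#'
#' @param model an `mt_demographic_model`.
#' @param params named parameter vector (e.g. from [draw_model_params()]).
#' @param mut_model mutation model.
#' @param seed optional local seed.
#' @param fst_mode fixation-index distance mode, see [simulate_dataset()].
#' @return a named numeric vector.
#' @export
simulate_model_stats <- function(model, params, mut_model = mutation_model(),
                                 seed = NULL,
                                 fst_mode = c("pairwise_diff",
                                              "haplotype_freq")) {
  fst_mode <- match.arg(fst_mode)
  tips <- compile_model_tips(model)
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  root_seq <- unname(base_code[rcrs_window()])
  cat_rates <- discrete_gamma_rates(mut_model$gamma_shape,
                                    mut_model$n_categories)
  inst <- instantiate_model(model, params)
  res <- with_seed(seed, simulate_hap_ids(
    tips$tip_age, tips$tip_deme0, inst$deme, inst$ev, mut_model, root_seq,
    cat_rates))
  summary_stats_from_ids(res$hap_id, tips$tip_group, model$groups,
                         model$fst_pairs, hap_seq = res$hap_seq,
                         fst_mode = fst_mode)
}
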