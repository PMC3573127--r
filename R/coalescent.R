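#' HVR-I finite-sites mutation model
#'
#' Defaults follow the standard serial-simulation parameterisation for the
#' 354-site HVR-I window: per-site per-generation substitution rate 7.5e-6, a
#' transition/transversion ratio of 0.9841 and gamma-distributed rate
#' heterogeneity across sites (shape 0.205, discretised into 10 mean-one
#' categories), with a generation time of 25 years. Mutations are recurrent
#' (finite sites): a site can change repeatedly and revert.
#'
#' @param L number of sites.
#' @param mu substitution rate per site per generation.
#' @param titv transition/transversion ratio.
#' @param gamma_shape shape of the gamma distribution of site rates.
#' @param n_categories number of discrete rate categories.
#' @param generation_years generation time in years (bookkeeping only; the
#'   simulator works in generations).
#' @return a list of class `mt_mutation_model`.
#' @export
mutation_model <- function(L = 354, mu = 7.5e-6, titv = 0.9841,
                           gamma_shape = 0.205, n_categories = 10,
                           generation_years = 25) {
  stopifnot(L >= 1, mu >= 0, titv > 0, gamma_shape > 0, n_categories >= 1)
  structure(list(L = as.integer(L), mu = mu, titv = titv,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 generation_years = generation_years),
            class = "mt_mutation_model")
}

#' Discrete mean-one gamma rate categories
#'
#' Equal-probability discretisation of a mean-one gamma distribution: category
#' `i` carries the conditional mean of the distribution between the
#' `(i-1)/k` and `i/k` quantiles, so the category mean is exactly one.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return a numeric vector of `k` rates with mean one.
#' @export
discrete_gamma_rates <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1) return(1)
  borders <- stats::qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
  upper <- stats::pgamma(borders[-1], shape + 1, rate = shape)
  lower <- stats::pgamma(borders[-(k + 1)], shape + 1, rate = shape)
  k * (upper - lower)
}

#' Specify a deme for the serial coalescent
#'
#' Sizes are haploid (mtDNA gene-copy) effective sizes. A deme either has
#' constant size `ne_modern`, or grows exponentially such that its size
#' `anchor_time` generations ago equals `anchor_ne` (backward in time the
#' size then stays constant at `anchor_ne`, the ancestral population).
#'
#' @param label deme label.
#' @param ne_modern present-day haploid effective size (> 0).
#' @param anchor_ne ancestral size the trajectory is anchored to; `NULL` for
#'   a constant-size deme.
#' @param anchor_time age of the anchor in generations.
#' @return a list of class `mt_deme`.
#' @export
deme_spec <- function(label, ne_modern, anchor_ne = NULL,
                      anchor_time = 1500) {
  if (!is.numeric(ne_modern) || ne_modern <= 0) {
    abort("`ne_modern` must be positive.")
  }
  if (is.null(anchor_ne)) {
    growth <- 0
    anchor_time <- Inf
  } else {
    stopifnot(anchor_ne > 0, anchor_time > 0)
    growth <- log(ne_modern / anchor_ne) / anchor_time
  }
  structure(list(label = label, ne_modern = ne_modern, growth = growth,
                 anchor_time = anchor_time), class = "mt_deme")
}

#' Demographic events
#'
#' `migration_pulse()` is a single mass-migration event: backward in time, at
#' `time`, every lineage of the `sink` deme moves to the `source` deme
#' independently with probability `fraction` (forward in time, a fraction of
#' the sink gene pool arrived from the source at that date).
#' `divergence_event()` merges the `of` deme into `into` at `time` (forward in
#' time, `of` split from `into`).
#'
#' @param time event age in generations (> 0).
#' @param sink,source,of,into deme labels.
#' @param fraction migrant fraction in `[0, 1]`.
#' @return an event list consumed by [simulate_genealogy()].
#' @export
migration_pulse <- function(time, sink, source, fraction) {
  stopifnot(time > 0, fraction >= 0, fraction <= 1)
  list(type = "pulse", time = time, from = sink, to = source,
       prob = fraction)
}

#' @rdname migration_pulse
#' @export
divergence_event <- function(time, of, into) {
  stopifnot(time > 0)
  list(type = "merge", time = time, from = of, to = into, prob = 1)
}

#' Simulate a serial-coalescent genealogy
#'
#' Standard coalescent with pairwise rate `1/Ne(t)` per generation within each
#' deme, heterochronous tips entering the process at their sampling age,
#' exponential growth handled by time rescaling, and time-ordered
#' mass-migration / divergence events.
#'
#' @param samples a data frame with columns `deme` (label), `age` (sampling
#'   age in generations) and `n` (number of tips), one row per sampling
#'   event; or a bare count for a single modern sample.
#' @param demes a list of [deme_spec()] objects (or a single one).
#' @param events a list of [migration_pulse()] / [divergence_event()] items.
#' @param seed optional seed applied locally (the caller's RNG stream is
#'   preserved); with `NULL` the global RNG stream is used.
#' @return an object of class `mt_genealogy`: `parent` (1-based, `NA` at the
#'   root), `age` per node, `n_tip`, and per-tip `tip_age`, `tip_deme`,
#'   `tip_group`. Tips are nodes `1..n_tip`.
#' @examples
#' g <- simulate_genealogy(5, deme_spec("pop", 1000), seed = 1)
#' tmrca(g)
#' @export
simulate_genealogy <- function(samples, demes, events = list(), seed = NULL) {
  if (inherits(demes, "mt_deme")) demes <- list(demes)
  labels <- vapply(demes, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("duplicate deme labels.")
  if (is.numeric(samples) && length(samples) == 1) {
    samples <- tibble::tibble(deme = labels[1], age = 0, n = samples)
  }
  stopifnot(is.data.frame(samples),
            all(c("deme", "age", "n") %in% names(samples)))
  if (sum(samples$n) < 1) abort("sampling schedule is empty.")
  if (any(samples$age < 0)) abort("sampling ages must be non-negative.")
  bad <- setdiff(samples$deme, labels)
  if (length(bad)) {
    abort(sprintf("samples reference unknown deme(s): %s",
                  paste(bad, collapse = ", ")))
  }

  tip_age <- rep(samples$age, samples$n)
  tip_deme <- rep(match(samples$deme, labels) - 1L, samples$n)
  tip_group <- rep(
    if ("group" %in% names(samples)) samples$group else
      paste0(samples$deme, "@", samples$age),
    samples$n)

  ev <- normalise_events(events, labels)
  res <- with_seed(seed, cpp_simulate_genealogy(
    tip_age, tip_deme,
    vapply(demes, `[[`, numeric(1), "ne_modern"),
    vapply(demes, `[[`, numeric(1), "growth"),
    vapply(demes, `[[`, numeric(1), "anchor_time"),
    ev$time, ev$type, ev$from, ev$to, ev$prob
  ))
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, age = res$node_time, n_tip = res$n_tip,
                 tip_age = tip_age, tip_deme = labels[tip_deme + 1L],
                 tip_group = tip_group),
            class = "mt_genealogy")
}

normalise_events <- function(events, labels) {
  if (length(events) && !is.null(events$type)) events <- list(events)
  if (!length(events)) {
    return(list(time = numeric(0), type = integer(0), from = integer(0),
                to = integer(0), prob = numeric(0)))
  }
  time <- vapply(events, `[[`, numeric(1), "time")
  ord <- order(time)
  events <- events[ord]
  from <- match(vapply(events, `[[`, character(1), "from"), labels) - 1L
  to <- match(vapply(events, `[[`, character(1), "to"), labels) - 1L
  if (anyNA(from) || anyNA(to)) abort("event references unknown deme label.")
  list(time = time[ord],
       type = ifelse(vapply(events, `[[`, character(1), "type") == "pulse",
                     0L, 1L),
       from = from, to = to,
       prob = vapply(events, `[[`, numeric(1), "prob"))
}

#' @export
print.mt_genealogy <- function(x, ...) {
  cat(sprintf("<mt_genealogy> %d tips (ages %s), TMRCA %.1f generations\n",
              x$n_tip, paste(unique(x$tip_age), collapse = "/"), tmrca(x)))
  invisible(x)
}

#' Genealogy summaries
#'
#' `tmrca()` is the age of the root; `total_branch_length()` the sum of all
#' branch lengths in generations.
#'
#' @param g an `mt_genealogy`.
#' @return a single number.
#' @export
tmrca <- function(g) max(g$age)

#' @rdname tmrca
#' @export
total_branch_length <- function(g) {
  ok <- !is.na(g$parent)
  sum(g$age[g$parent[ok]] - g$age[ok])
}

#' Convert a genealogy to an ape phylo tree
#'
#' @param g an `mt_genealogy`.
#' @return an object of class `phylo` (requires the ape package).
#' @export
as_phylo <- function(g) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the ape package is required for as_phylo().")
  }
  n <- g$n_tip
  # ape convention: tips 1..n, root n+1, other internal nodes follow
  root_old <- which(is.na(g$parent))
  internal_old <- c(root_old, setdiff(seq_along(g$parent), c(seq_len(n),
                                                             root_old)))
  remap <- integer(length(g$parent))
  remap[seq_len(n)] <- seq_len(n)
  remap[internal_old] <- n + seq_along(internal_old)
  ok <- which(!is.na(g$parent))
  edge <- cbind(remap[g$parent[ok]], remap[ok])
  tr <- list(edge = edge,
             edge.length = g$age[g$parent[ok]] - g$age[ok],
             tip.label = paste0("t", seq_len(n)),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Drop mutations on a genealogy under the finite-sites model
#'
#' Places substitutions as a Poisson process along every branch with per-site
#' rate `mu` times the site's gamma rate category; at each event the new base
#' is a transition with probability `titv/(1+titv)`, otherwise one of the two
#' transversions. Site categories are drawn once per call. Returns the tip
#' haplotypes as variant sets relative to the root (reference) sequence.
#'
#' @param tree an `mt_genealogy`.
#' @param model an [mutation_model()].
#' @param reference root sequence as a named base vector ([rcrs_window()]).
#' @param seed optional local seed.
#' @param keep_sequences also return the full tip base matrix?
#' @return a tibble with one row per tip: `tip`, `age`, `deme`, `group`,
#'   `hap_id` (dense haplotype class id), `key` (resolved-variant key) and,
#'   when requested, an attached `sequences` attribute (tips x sites matrix).
#' @export
mutate_sequences <- function(tree, model = mutation_model(),
                             reference = rcrs_window(), seed = NULL,
                             keep_sequences = FALSE) {
  stopifnot(inherits(tree, "mt_genealogy"),
            inherits(model, "mt_mutation_model"))
  if (length(reference) != model$L) {
    abort("reference length does not match the mutation model.")
  }
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  root_seq <- unname(base_code[reference])
  res <- with_seed(seed, {
    rates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
    site_rate <- rates[sample.int(model$n_categories, model$L,
                                  replace = TRUE)]
    parent0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
    cpp_mutate_tree(parent0, tree$age, tree$n_tip, root_seq, site_rate,
                    model$mu, model$titv, TRUE)
  })
  seqs <- res$tip_seq
  pos <- as.integer(names(reference))
  bases <- names(base_code)
  keys <- vapply(seq_len(tree$n_tip), function(i) {
    diff <- which(seqs[i, ] != root_seq)
    if (!length(diff)) return("")
    paste(paste0(pos[diff], bases[seqs[i, diff] + 1L]), collapse = "-")
  }, character(1))
  out <- tibble::tibble(
    tip = seq_len(tree$n_tip),
    age = tree$tip_age,
    deme = tree$tip_deme,
    group = tree$tip_group,
    hap_id = res$hap_id,
    key = keys
  )
  attr(out, "n_mutations") <- res$n_mutations
  attr(out, "n_transitions") <- res$n_transitions
  attr(out, "n_transversions") <- res$n_transversions
  if (keep_sequences) attr(out, "sequences") <- seqs
  out
}

# fast path used inside ABC loops: haplotype ids and unique-haplotype
# sequences only, no tibbles
simulate_hap_ids <- function(tip_age, tip_deme0, deme_par, ev, model,
                             root_seq, cat_rates) {
  g <- cpp_simulate_genealogy(tip_age, tip_deme0, deme_par$ne0,
                              deme_par$growth, deme_par$anchor,
                              ev$time, ev$type, ev$from, ev$to, ev$prob)
  site_rate <- cat_rates[sample.int(length(cat_rates), model$L,
                                    replace = TRUE)]
  cpp_mutate_tree(g$parent, g$node_time, g$n_tip, root_seq, site_rate,
                  model$mu, model$titv, FALSE)
}

#' Simulate a dataset and its summary statistics
#'
#' Simulates one genealogy with mutations under a concrete demographic model
#' instance, groups the tips into population samples by their sampling label,
#' and returns the summary-statistic vector: corrected haplotype diversity
#' `h_<group>` per sample and AMOVA fixation index `fst_<a>_<b>` per sample
#' pair. Fixation indices default to pairwise-difference distances
#' (sequence-level Phi_ST, matching how the observed fixture values were
#' computed); haplotype-identity (0/1) distances are available via
#' `fst_mode`.
#'
#' @param samples sampling schedule as in [simulate_genealogy()] (a `group`
#'   column names the statistics).
#' @param demes,events demographic structure as in [simulate_genealogy()].
#' @param model a [mutation_model()].
#' @param seed optional local seed.
#' @param pairs optional 2-column matrix/data frame of group pairs for which
#'   to compute fixation indices (default: all pairs).
#' @param fst_mode `"pairwise_diff"` (default) or `"haplotype_freq"`.
#' @return a named numeric vector of summary statistics.
#' @export
simulate_dataset <- function(samples, demes, events = list(),
                             model = mutation_model(), seed = NULL,
                             pairs = NULL,
                             fst_mode = c("pairwise_diff", "haplotype_freq")) {
  fst_mode <- match.arg(fst_mode)
  sim <- with_seed(seed, {
    g <- simulate_genealogy(samples, demes, events)
    mutate_sequences(g, model, keep_sequences = TRUE)
  })
  groups <- unique(sim$group)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(groups, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  # unique-haplotype sequences in dense id order
  seqs <- attr(sim, "sequences")
  hap_seq <- seqs[!duplicated(sim$hap_id), , drop = FALSE]
  hap_seq <- hap_seq[order(sim$hap_id[!duplicated(sim$hap_id)]), ,
                     drop = FALSE]
  summary_stats_from_ids(sim$hap_id, sim$group, groups, pairs,
                         hap_seq = hap_seq, fst_mode = fst_mode)
}

# h per group and AMOVA F_ST per requested pair, from dense haplotype ids
# (and, for pairwise-difference mode, the unique-haplotype base matrix)
summary_stats_from_ids <- function(hap_id, group, groups, pairs,
                                   hap_seq = NULL,
                                   fst_mode = "pairwise_diff") {
  ids <- split(hap_id, factor(group, levels = groups))
  nh <- max(hap_id)
  counts <- lapply(ids, tabulate, nbins = nh)
  h <- vapply(counts, diversity_from_counts, numeric(1))
  names(h) <- paste0("h_", groups)
  fst <- numeric(nrow(pairs))
  if (nrow(pairs)) {
    if (fst_mode == "pairwise_diff") {
      if (is.null(hap_seq)) abort("pairwise_diff mode needs hap_seq.")
      Fs <- lapply(counts, function(cnt) cpp_base_counts(hap_seq, cnt))
      ns <- vapply(counts, sum, numeric(1))
      for (i in seq_len(nrow(pairs))) {
        a <- pairs[i, 1]
        b <- pairs[i, 2]
        fst[i] <- amova_fst_sitewise(Fs[[a]], Fs[[b]], ns[[a]], ns[[b]])
      }
    } else {
      for (i in seq_len(nrow(pairs))) {
        fst[i] <- amova_fst_counts(counts[[pairs[i, 1]]],
                                   counts[[pairs[i, 2]]])
      }
    }
    names(fst) <- paste0("fst_", pairs[, 1], "_", pairs[, 2])
  }
  c(h, fst)
}
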