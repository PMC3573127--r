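#' Recipe for a synthetic modern population pool
#'
#' Describes a modern comparative population to synthesise: its size, target
#' haplogroup composition, target corrected haplotype diversity, and
#' optionally planted haplotypes to embed verbatim (e.g. to plant exact
#' matches for sharing analyses).
#'
#' @param label population label.
#' @param n number of individuals.
#' @param hg_composition named vector of haplogroup frequencies summing to
#'   one; names must be assignable classes of the motif table.
#' @param diversity_target desired corrected haplotype diversity, or `NULL`
#'   to skip diversity targeting (maximal diversity is then used).
#' @param planted optional data frame with columns `motif` and `count`.
#' @param seed integer seed; generation is a pure function of (recipe, seed).
#' @return a list of class `mt_pool_recipe`.
#' @export
pool_recipe <- function(label, n, hg_composition, diversity_target = NULL,
                        planted = NULL, seed = 1) {
  n <- stopifnot_scalar_count(n, "n")
  if (n < 1) abort("`n` must be at least 1.")
  if (is.null(names(hg_composition)) ||
      abs(sum(hg_composition) - 1) > 1e-6 || any(hg_composition < 0)) {
    abort("`hg_composition` must be a named non-negative vector summing to 1.")
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("motif", "count") %in% names(planted)))
    if (sum(planted$count) > n) {
      abort("planted haplotypes exceed the pool size.")
    }
  }
  if (!is.null(diversity_target) &&
      (diversity_target < 0 || diversity_target > 1)) {
    abort("`diversity_target` must be in [0, 1].")
  }
  structure(list(label = label, n = n, hg_composition = hg_composition,
                 diversity_target = diversity_target, planted = planted,
                 seed = seed),
            class = "mt_pool_recipe")
}

#' Built-in recipes emulating the modern comparison populations
#'
#' Compositions are stylised European (NEE, CE) and Saami profiles chosen to
#' be realistic for the region (H-rich European pools; a Saami pool dominated
#' by U5b and V with a minor east-Eurasian component); sizes and diversity
#' targets are the observed fixture values (NEE n=621 h=0.98, Saami n=118
#' h=0.81, CE n=1030 h=0.97).
#'
#' @param seed base seed; each recipe uses an offset of it.
#' @return a named list of [pool_recipe()]s.
#' @export
default_pool_recipes <- function(seed = 1) {
  european <- c(H = 0.43, U5a = 0.06, U5b = 0.06, U4 = 0.04, U2 = 0.02,
                K = 0.06, J = 0.09, T = 0.09, V = 0.04, W = 0.02, X = 0.02,
                I = 0.02, HV = 0.02, N1 = 0.01, misc = 0.02)
  saami <- c(U5b = 0.47, V = 0.34, Z = 0.03, D = 0.04, H = 0.05, U5a = 0.03,
             U4 = 0.04)
  list(
    NEE = pool_recipe("NEE", 621, european, diversity_target = 0.98,
                      seed = seed),
    saa = pool_recipe("saa", 118, saami, diversity_target = 0.81,
                      seed = seed + 1),
    CE = pool_recipe("CE", 1030, european, diversity_target = 0.97,
                     seed = seed + 2)
  )
}

#' Generate a synthetic modern population pool
#'
#' Synthesises a haplotype table with the recipe's haplogroup composition and
#' corrected haplotype diversity (within ±0.01 of the target). Haplotype
#' class sizes are chosen by an analytic solver (balanced class sizes whose
#' sum of squared frequencies matches the target homozygosity), classes are
#' realised as the haplogroup's defining motif plus private variants at
#' positions unused by any motif definition (so every generated haplotype is
#' assigned back to its intended haplogroup), and planted haplotypes are
#' embedded verbatim. Output is reproducible from the recipe seed and passes
#' the same schema validation as user CSV input.
#'
#' @param recipe a [pool_recipe()].
#' @param motif_table haplogroup motif table.
#' @return a tibble in the haplotype-table schema (`sample_id`, `population`,
#'   `age_generations`, `motif`, `hg`, `key`).
#' @export
generate_modern_pool <- function(recipe, motif_table = load_hg_motifs()) {
  stopifnot(inherits(recipe, "mt_pool_recipe"))
  with_seed(recipe$seed, generate_modern_pool_impl(recipe, motif_table))
}

generate_modern_pool_impl <- function(recipe, motif_table) {
  n <- recipe$n
  planted <- recipe$planted
  planted_counts <- if (is.null(planted)) integer(0) else planted$count
  n_rest <- n - sum(planted_counts)

  # --- class-size solver ------------------------------------------------
  # corrected diversity h = n/(n-1) (1 - sum p^2)  =>  target sum of squared
  # counts R = n^2 (1 - h (n-1)/n), minus the planted contribution
  sizes <- integer(0)
  if (n_rest > 0) {
    if (is.null(recipe$diversity_target)) {
      sizes <- rep(1L, n_rest)
    } else {
      R_total <- n^2 * (1 - recipe$diversity_target * (n - 1) / n)
      R <- R_total - sum(planted_counts^2)
      sizes <- solve_class_sizes(n_rest, R)
    }
  }
  counts_all <- c(planted_counts, sizes)
  h_real <- diversity_from_counts(counts_all)
  if (!is.null(recipe$diversity_target) &&
      abs(h_real - recipe$diversity_target) > 0.01) {
    abort(sprintf(
      "diversity target %.3f unattainable for n = %d (best %.4f)",
      recipe$diversity_target, n, h_real))
  }

  # --- haplogroup quotas (largest remainder) -----------------------------
  quota <- recipe$hg_composition * n_rest
  cnt <- floor(quota)
  rem <- n_rest - sum(cnt)
  if (rem > 0) {
    extra <- order(quota - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  # assign classes (largest first) to the haplogroup with most open quota
  hg_of_class <- character(length(sizes))
  open <- cnt
  for (i in order(sizes, decreasing = TRUE)) {
    j <- which.max(open)
    hg_of_class[i] <- names(recipe$hg_composition)[j]
    open[j] <- open[j] - sizes[i]
  }

  # --- realise classes as motifs ----------------------------------------
  used_positions <- unique(unlist(lapply(motif_table$variants,
                                         function(v) v$position)))
  if (!is.null(planted)) {
    pl_pos <- unlist(lapply(planted$motif,
                            function(m) parse_motif(m)$variants$position))
    used_positions <- unique(c(used_positions, pl_pos))
  }
  free <- setdiff(seq.int(HVR1_START, HVR1_END), used_positions)
  free <- sample(free)          # seeded shuffle for variety
  combos <- private_variant_combos(length(sizes), free)

  class_motifs <- character(length(sizes))
  for (i in seq_along(sizes)) {
    hg <- hg_of_class[i]
    base <- motif_table$motif[match_class_representative(hg, motif_table)]
    priv <- sprintf("%03dT", combos[[i]] - 16000L)
    toks <- c(if (nzchar(base)) strsplit(base, "-", fixed = TRUE)[[1]], priv)
    pos <- as.integer(sub("[A-Za-z]$", "", toks)) # order by position
    class_motifs[i] <- paste(toks[order(pos)], collapse = "-")
  }

  rows <- tibble::tibble(
    motif = c(if (is.null(planted)) character(0) else
      rep(planted$motif, planted$count), rep(class_motifs, sizes)),
    hg = NA_character_
  )
  rows <- rows[sample.int(nrow(rows)), ]
  rows$hg <- vapply(rows$motif, assign_haplogroup, character(1),
                    motif_table = motif_table, USE.NAMES = FALSE)
  out <- tibble::tibble(
    sample_id = sprintf("%s_%04d", recipe$label, seq_len(nrow(rows))),
    population = recipe$label,
    age_generations = 0,
    motif = rows$motif,
    hg = rows$hg
  )
  out$key <- motif_keys(out$motif)
  attr(out, "recipe") <- recipe
  attr(out, "realised_diversity") <- h_real
  out
}

# class index of a haplogroup label in the motif table, accepting either a
# fine label or a pooled class name
match_class_representative <- function(hg, motif_table) {
  i <- match(hg, motif_table$hg)
  if (!is.na(i)) return(i)
  i <- match(hg, motif_table$class)
  if (!is.na(i)) return(i)
  abort(sprintf("no motif definition for haplogroup '%s'", hg))
}

# sizes of k classes summing to n whose sum of squares approximates R,
# using the balanced configuration (all classes of size ~n/k)
solve_class_sizes <- function(n, R) {
  R <- min(max(R, n), n^2)
  ss_balanced <- function(k) {
    q <- n %/% k
    r <- n %% k
    r * (q + 1)^2 + (k - r) * q^2
  }
  # sum of squares decreases monotonically in k; binary search then refine
  lo <- 1L
  hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ss_balanced(mid) > R) lo <- mid else hi <- mid
  }
  k <- if (abs(ss_balanced(lo) - R) < abs(ss_balanced(hi) - R)) lo else hi
  q <- n %/% k
  r <- n %% k
  as.integer(c(rep(q + 1, r), rep(q, k - r)))
}

# the i-th distinct non-empty subset (singletons first, then pairs) of the
# free-position pool, for up to length(f) + choose(length(f), 2) classes
private_variant_combos <- function(k, free) {
  if (k == 0) return(list())
  nf <- length(free)
  if (k > nf + choose(nf, 2)) {
    abort("not enough free positions to realise this many haplotype classes.")
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    if (i <= nf) {
      out[[i]] <- free[i]
    } else {
      j <- i - nf - 1L          # 0-based pair index
      a <- 1L
      skip <- j
      while (skip >= nf - a) {
        skip <- skip - (nf - a)
        a <- a + 1L
      }
      out[[i]] <- c(free[a], free[a + 1L + skip])
    }
  }
  out
}

#' Generate a synthetic haplogroup-frequency matrix
#'
#' Draws population rows as Dirichlet perturbations around each cluster's
#' mean 19-variable spectrum, for exercising the spectrum PCA. A
#' `concentration` of `Inf` reproduces the cluster mean exactly (zero
#' noise).
#'
#' @param cluster_specs a list of cluster descriptions, each a list with
#'   `label`, `mean` (named frequency vector over the 19 classes, or a
#'   subset -- missing classes get zero), `n_rows`, and optional
#'   `concentration` (Dirichlet precision, default 200).
#' @param seed integer seed.
#' @return a tibble with columns `population`, `cluster`, then the 19 class
#'   frequencies (rows sum to one).
#' @export
generate_frequency_matrix <- function(cluster_specs, seed = 1) {
  if (length(cluster_specs) < 2) abort("need at least two cluster specs.")
  with_seed(seed, {
    rows <- purrr::imap(cluster_specs, function(spec, idx) {
      label <- spec$label %||% paste0("cluster", idx)
      n_rows <- spec$n_rows %||% 5L
      conc <- spec$concentration %||% 200
      mean <- rep(0, length(SPECTRUM_CLASSES))
      names(mean) <- SPECTRUM_CLASSES
      bad <- setdiff(names(spec$mean), SPECTRUM_CLASSES)
      if (length(bad)) {
        abort(sprintf("unknown spectrum class(es): %s",
                      paste(bad, collapse = ", ")))
      }
      mean[names(spec$mean)] <- spec$mean
      if (sum(mean) <= 0) abort("degenerate cluster spec: empty composition.")
      mean <- mean / sum(mean)
      draws <- t(vapply(seq_len(n_rows), function(i) {
        if (is.infinite(conc)) return(mean)
        g <- stats::rgamma(length(mean), shape = mean * conc)
        if (sum(g) <= 0) return(mean)
        g / sum(g)
      }, numeric(length(mean))))
      colnames(draws) <- SPECTRUM_CLASSES
      dplyr::bind_cols(
        tibble::tibble(population = sprintf("%s_%02d", label, seq_len(n_rows)),
                       cluster = label),
        tibble::as_tibble(draws)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a pseudo-observed summary-statistic vector
#'
#' One simulated dataset under a demographic model at known ("true")
#' parameter values, labelled with its provenance -- the input for parameter-
#' and model-recovery experiments.
#'
#' @param model an `mt_demographic_model`.
#' @param true_params named parameter vector inside the prior support.
#' @param seed integer seed.
#' @param mut_model mutation model.
#' @return a named statistic vector with attributes `model` and
#'   `true_params`.
#' @export
generate_pseudo_observed <- function(model, true_params, seed = 1,
                                     mut_model = mutation_model()) {
  for (p in names(model$priors)) {
    if (is.na(true_params[p]) ||
        true_params[p] < model$priors[[p]][1] ||
        true_params[p] > model$priors[[p]][2]) {
      abort(sprintf("true parameter '%s' outside the prior support", p))
    }
  }
  stats <- simulate_model_stats(model, true_params, mut_model = mut_model,
                                seed = seed)
  attr(stats, "model") <- model$name
  attr(stats, "true_params") <- true_params
  stats
}
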