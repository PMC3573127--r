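# Resolve the haplotype-identity keys of a population input. Accepts a data
# frame carrying `key` (preferred) or `motif`, or a bare character vector of
# keys/motifs, or a named count vector via list(counts = ...conversion below).
population_keys <- function(data) {
  if (is.data.frame(data)) {
    if ("key" %in% names(data)) return(data$key)
    if ("motif" %in% names(data)) return(motif_keys(data$motif))
    abort("`data` must carry a `key` or `motif` column.")
  }
  if (is.character(data)) return(data)
  abort("population input must be a data frame or a character vector.")
}

#' Haplotype diversity
#'
#' Nei's gene (haplotype) diversity: the probability that two randomly drawn
#' members carry different haplotypes. The corrected (unbiased) form is
#' `h = n/(n-1) * (1 - sum(p_i^2))` over haplotype class frequencies `p_i`.
#'
#' @param data a population: data frame with a `key` or `motif` column, or a
#'   character vector of haplotype identifiers.
#' @param corrected apply the `n/(n-1)` small-sample correction (default).
#' @return a single number in `[0, 1]`.
#' @examples
#' haplotype_diversity(c("a", "a", "b"))           # 2/3 with correction
#' haplotype_diversity(rep("a", 5))                # 0
#' @export
haplotype_diversity <- function(data, corrected = TRUE) {
  keys <- population_keys(data)
  if (!length(keys)) abort("empty population.")
  diversity_from_counts(as.integer(table(keys)), corrected = corrected)
}

#' @rdname haplotype_diversity
#' @param counts integer vector of haplotype class counts.
#' @export
diversity_from_counts <- function(counts, corrected = TRUE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (corrected && n < 2) {
    abort("corrected haplotype diversity requires n >= 2.")
  }
  if (n == 0) abort("empty population.")
  h <- 1 - sum((counts / n)^2)
  if (corrected) h <- h * n / (n - 1)
  h
}

#' Pairwise fixation index F_ST between two populations
#'
#' AMOVA-based fixation index (the ratio of the among-population variance
#' component to the total) computed from inter-haplotype distances. In
#' `haplotype_freq` mode the distance between two haplotypes is 0/1
#' (identical/different); in `pairwise_diff` mode it is the number of resolved
#' differences over the intersection of the sequenced windows. Estimates can
#' be slightly negative in small samples and are reported as computed. When
#' there is no haplotypic variation at all, 0 is returned.
#'
#' @param pop_a,pop_b populations as in [haplotype_diversity()].
#' @param mode distance mode, `"haplotype_freq"` (default) or
#'   `"pairwise_diff"`.
#' @return a single number (symmetric in its arguments).
#' @export
pairwise_fst <- function(pop_a, pop_b,
                         mode = c("haplotype_freq", "pairwise_diff")) {
  mode <- match.arg(mode)
  ka <- population_keys(pop_a)
  kb <- population_keys(pop_b)
  if (!length(ka) || !length(kb)) abort("empty population.")
  haps <- unique(c(ka, kb))
  ca <- tabulate(match(ka, haps), nbins = length(haps))
  cb <- tabulate(match(kb, haps), nbins = length(haps))
  # pairwise difference counts enter the AMOVA as the squared distances
  d2 <- if (mode == "haplotype_freq") NULL else key_difference_matrix(haps)
  amova_fst_counts(ca, cb, d2)
}

# squared-distance AMOVA on two populations given per-haplotype counts and the
# matrix of squared inter-haplotype distances; d2 = NULL means the 0/1
# haplotype-frequency distance, for which the quadratic form has the closed
# form (n^2 - sum(c^2)) / (2n)
amova_fst_counts <- function(ca, cb, d2 = NULL) {
  na <- sum(ca)
  nb <- sum(cb)
  ct <- ca + cb
  # SSD(x) = (1 / 2n) * sum_ij c_i c_j d2_ij  (ordered double sum)
  ssd <- if (is.null(d2)) {
    function(cnt, n) (n^2 - sum(cnt^2)) / (2 * n)
  } else {
    function(cnt, n) drop(cnt %*% d2 %*% cnt) / (2 * n)
  }
  amova_phi(ssd(ct, na + nb), ssd(ca, na) + ssd(cb, nb), na, nb)
}

# the same AMOVA with pairwise-difference distances, decomposed per site from
# base-count matrices (sites x 4): sum_ij c_i c_j pi_ij =
# sum_s (n^2 - sum_b f_sb^2)
amova_fst_sitewise <- function(Fa, Fb, na, nb) {
  ssd <- function(F, n) sum(n^2 - rowSums(F^2)) / (2 * n)
  amova_phi(ssd(Fa + Fb, na + nb), ssd(Fa, na) + ssd(Fb, nb), na, nb)
}

# two-population AMOVA variance components -> Phi_ST
amova_phi <- function(ssd_total, ssd_within, na, nb) {
  if (ssd_total <= 0) return(0)          # no variation at all
  n_tot <- na + nb
  sigma_w <- ssd_within / (n_tot - 2)
  ms_among <- ssd_total - ssd_within     # / (P - 1) with P = 2
  n_prime <- n_tot - (na^2 + nb^2) / n_tot
  sigma_a <- (ms_among - sigma_w) / n_prime
  sigma_a / (sigma_a + sigma_w)
}

# number of resolved pairwise differences between comparison keys
key_difference_matrix <- function(keys) {
  split_key <- function(k) if (k == "") character(0) else strsplit(k, "-", fixed = TRUE)[[1]]
  sets <- lapply(keys, split_key)
  m <- matrix(0, length(keys), length(keys))
  for (i in seq_along(keys)) {
    for (j in seq_len(i - 1L)) {
      d <- length(setdiff(sets[[i]], sets[[j]])) +
        length(setdiff(sets[[j]], sets[[i]]))
      # two different bases at one position count once, not twice
      pi <- sub("[ACGT]$", "", setdiff(sets[[i]], sets[[j]]))
      pj <- sub("[ACGT]$", "", setdiff(sets[[j]], sets[[i]]))
      d <- d - length(intersect(pi, pj))
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' All pairwise F_ST values among populations of a table
#'
#' @param data a data frame of members with a population column and `key` or
#'   `motif` column.
#' @param group name of the population column.
#' @inheritParams pairwise_fst
#' @return a tibble with columns `pop_a`, `pop_b`, `fst`.
#' @export
fst_matrix <- function(data, group = "population",
                       mode = c("haplotype_freq", "pairwise_diff")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), group %in% names(data))
  keys <- population_keys(data)
  pops <- split(keys, data[[group]])
  labs <- names(pops)
  if (length(labs) < 2) abort("need at least two populations.")
  pairs <- utils::combn(labs, 2)
  tibble::tibble(
    pop_a = pairs[1, ],
    pop_b = pairs[2, ],
    fst = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                          ~ pairwise_fst(pops[[.x]], pops[[.y]], mode = mode))
  )
}
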