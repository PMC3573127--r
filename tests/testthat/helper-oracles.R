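# Independent brute-force AMOVA oracle: literal per-individual double loops
# over squared inter-haplotype distances, no shared code with the package's
# count-based implementation.
oracle_amova_fst <- function(keys_a, keys_b, dist_fun = function(x, y) {
  as.numeric(x != y)
}) {
  na <- length(keys_a)
  nb <- length(keys_b)
  keys <- c(keys_a, keys_b)
  n <- na + nb
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d2[i, j] <- dist_fun(keys[i], keys[j])^2
    }
  }
  ssd <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ssd_t <- ssd(seq_len(n))
  ssd_w <- ssd(seq_len(na)) + ssd(na + seq_len(nb))
  if (ssd_t <= 0) return(0)
  sigma_w <- ssd_w / (n - 2)
  ms_among <- (ssd_t - ssd_w) / 1
  n_prime <- (n - (na^2 + nb^2) / n) / 1
  sigma_a <- (ms_among - sigma_w) / n_prime
  sigma_a / (sigma_a + sigma_w)
}

# number of resolved differences between two comparison keys (independent of
# the package's key_difference_matrix)
oracle_key_diff <- function(x, y) {
  sx <- if (nzchar(x)) strsplit(x, "-")[[1]] else character(0)
  sy <- if (nzchar(y)) strsplit(y, "-")[[1]] else character(0)
  px <- sub("[A-Z]$", "", sx)
  py <- sub("[A-Z]$", "", sy)
  bx <- stats::setNames(sub("^[0-9]+", "", sx), px)
  by <- stats::setNames(sub("^[0-9]+", "", sy), py)
  pos <- union(px, py)
  sum(vapply(pos, function(p) {
    a <- if (p %in% px) bx[[p]] else "."
    b <- if (p %in% py) by[[p]] else "."
    a != b
  }, logical(1)))
}

# analytic CDF of the pairwise (n = 2) coalescence time under a single deme
# with backward size N(t) = ne0 * exp(-r * min(t, anchor))
oracle_t2_cdf <- function(t, ne0, r, anchor) {
  lam <- function(t) {
    t1 <- pmin(t, anchor)
    base <- if (r != 0) (exp(r * t1) - 1) / (ne0 * r) else t1 / ne0
    extra <- pmax(t - anchor, 0) / (ne0 * exp(-r * anchor))
    base + extra
  }
  1 - exp(-vapply(t, lam, numeric(1)))
}

# small deterministic toy populations used across tests
toy_pop <- function(keys, population = "pop") {
  tibble::tibble(
    sample_id = paste0(population, seq_along(keys)),
    population = population,
    key = keys
  )
}
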