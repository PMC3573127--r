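fx <- load_ancient_fixture()
uz <- fx[fx$population == "aUzPo", ]
bo <- fx[fx$population == "aBOO", ]

test_that("haplogroup spectra pool sub-haplogroups and conserve counts", {
  sp <- haplogroup_spectrum(uz)
  expect_equal(sum(sp$freq), 1, tolerance = 1e-9)
  expect_equal(sum(sp$count), nrow(uz))
  expect_identical(sp$class, spectrum_classes())
  got <- stats::setNames(sp$count, sp$class)
  expect_equal(got[c("U4", "C", "U2", "U5a", "H")],
               c(U4 = 4L, C = 3L, U2 = 2L, U5a = 1L, H = 1L))

  sb <- haplogroup_spectrum(bo)
  expect_equal(sb$count[sb$class == "C"], 8L)   # 6 C* + 2 C5
  expect_equal(sum(sb$count), 23L)

  eas <- haplogroup_spectrum(rep("A", 7))
  expect_equal(eas$freq[eas$class == "EAS"], 1)
  expect_equal(sum(eas$freq[eas$class != "EAS"]), 0)

  expect_error(haplogroup_spectrum(character(0)), "empty")
  expect_error(haplogroup_spectrum(c("U5a", "??")), "pool")
})

test_that("printed integer percentages use round-half-up", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(36.3636), 36)
  sp <- spectrum_percent(haplogroup_spectrum(uz))
  pct <- stats::setNames(sp$percent, sp$class)
  expect_equal(pct[["C"]], 27)
  expect_equal(pct[["U2"]], 18)
  expect_equal(sum(pct[c("U2", "U4", "U5a")]), 63)  # U classes except U5b
})

test_that("regional totals split the aBOO spectrum 39/61", {
  reg <- spectrum_region_totals(haplogroup_spectrum(bo))
  expect_equal(reg$percent[reg$region == "European"], 39)
  expect_equal(reg$percent[reg$region == "Siberian"], 61)
})

test_that("haplotype diversity matches closed forms and is label-invariant", {
  expect_equal(haplotype_diversity(rep("x", 8)), 0)
  expect_equal(haplotype_diversity(letters[1:6]), 1)   # n/(n-1)*(1-1/n) = 1
  expect_equal(haplotype_diversity(c("a", "a", "b"), corrected = FALSE),
               1 - (4 + 1) / 9)
  # frozen hand computation: counts (2,3,1,1,3,1), n = 11
  expect_equal(haplotype_diversity(uz), 11 / 10 * (1 - 25 / 121),
               tolerance = 1e-12)
  expect_error(haplotype_diversity("a"), "n >= 2")
  # relabelling invariance
  expect_equal(haplotype_diversity(c("a", "a", "b", "c")),
               haplotype_diversity(c("z", "z", "q", "w")))
  # splitting a class never decreases diversity
  expect_gte(haplotype_diversity(c("a", "d", "b", "b")),
             haplotype_diversity(c("a", "a", "b", "b")) - 1e-12)
})

test_that("AMOVA F_ST reproduces the brute-force oracle on fixtures and
           random populations", {
  pops <- split(fx$key, fx$population)
  for (pair in list(c("aUzPo", "aBOO"))) {
    expect_equal(pairwise_fst(pops[[pair[1]]], pops[[pair[2]]]),
                 oracle_amova_fst(pops[[pair[1]]], pops[[pair[2]]]),
                 tolerance = 1e-9)
  }
  set.seed(42)
  for (i in 1:8) {
    a <- sample(letters[1:5], sample(3:25, 1), replace = TRUE)
    b <- sample(letters[2:7], sample(3:25, 1), replace = TRUE)
    expect_equal(pairwise_fst(a, b), oracle_amova_fst(a, b),
                 tolerance = 1e-9)
  }
})

test_that("F_ST endpoints: no variation gives 0, fixed difference gives 1,
           and the statistic is symmetric", {
  expect_equal(pairwise_fst(rep("a", 9), rep("a", 4)), 0)
  expect_equal(pairwise_fst(rep("a", 9), rep("b", 4)), 1)
  a <- c("a", "a", "b", "c")
  b <- c("b", "c", "c", "d", "d")
  expect_equal(pairwise_fst(a, b), pairwise_fst(b, a), tolerance = 1e-12)
})

test_that("pairwise-difference F_ST agrees with the oracle under sequence
           distances", {
  uzk <- uz$key
  bok <- bo$key
  expect_equal(
    pairwise_fst(uz, bo, mode = "pairwise_diff"),
    oracle_amova_fst(uzk, bok, dist_fun = function(x, y)
      sqrt(oracle_key_diff(x, y))),
    tolerance = 1e-9
  )
  # the sitewise decomposition equals the quadratic form on simulated data
  set.seed(7)
  sim <- simulate_dataset(
    tibble::tibble(deme = "p", age = c(0, 0), n = c(15, 15),
                   group = c("A", "B")),
    deme_spec("p", 400), model = mutation_model(mu = 5e-5), seed = 99
  )
  sim2 <- simulate_dataset(
    tibble::tibble(deme = "p", age = c(0, 0), n = c(15, 15),
                   group = c("A", "B")),
    deme_spec("p", 400), model = mutation_model(mu = 5e-5), seed = 99,
    fst_mode = "haplotype_freq"
  )
  expect_named(sim, c("h_A", "h_B", "fst_A_B"))
  expect_identical(sim[c("h_A", "h_B")], sim2[c("h_A", "h_B")])
})

test_that("PCA of spectra matches an independent eigendecomposition", {
  m <- rbind(
    c(0.6, 0.2, 0.1, 0.1),
    c(0.3, 0.3, 0.2, 0.2),
    c(0.1, 0.2, 0.4, 0.3),
    c(0.05, 0.15, 0.5, 0.3)
  )
  colnames(m) <- c("H", "U5a", "C", "D")
  rownames(m) <- paste0("p", 1:4)
  p <- pca_spectra(m)
  expect_equal(sum(p$variance$fraction), 1, tolerance = 1e-9)
  # oracle: eigen on the covariance of the centered matrix
  cm <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cm))
  scores_oracle <- cm %*% eig$vectors
  got <- as.matrix(p$scores[paste0("PC", 1:4)])
  for (j in 1:4) {
    expect_equal(abs(got[, j]), abs(scores_oracle[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # reconstruction from all components reproduces the centered matrix
  recon <- as.matrix(p$scores[paste0("PC", 1:4)]) %*%
    t(as.matrix(p$loadings[paste0("PC", 1:4)]))
  expect_equal(recon, unclass(cm), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA invariants: duplicated rows coincide; row permutation only
           permutes scores; degenerate input errors", {
  m <- rbind(a = c(0.7, 0.2, 0.1), b = c(0.2, 0.5, 0.3),
             b2 = c(0.2, 0.5, 0.3), c = c(0.1, 0.1, 0.8))
  colnames(m) <- c("H", "C", "D")
  p <- pca_spectra(m)
  expect_equal(unlist(p$scores[2, -1]), unlist(p$scores[3, -1]),
               tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  p2 <- pca_spectra(m[perm, ])
  for (j in seq_len(3)) {
    expect_equal(abs(p2$scores[[paste0("PC", j)]]),
                 abs(p$scores[[paste0("PC", j)]][perm]), tolerance = 1e-9)
  }
  expect_error(pca_spectra(m[1:2, ]), "three")
  expect_error(pca_spectra(m[c(1, 1, 1), ]), "zero-variance")
  expect_s3_class(glance(p), "tbl_df")
  expect_equal(nrow(tidy(p, "variance")), 3)
})

test_that("genetic distance profiles: zero at identity, symmetric, Nei
           closed form", {
  x <- c(A = 1, B = 0)
  y <- c(A = 0.5, B = 0.5)
  pools <- rbind(x = x, y = y)
  d <- distance_profile(x, pools)
  expect_equal(d$distance[1], 0)
  expect_equal(d$distance[2], -log(0.5 / sqrt(1 * 0.5)), tolerance = 1e-12)
  # symmetry
  expect_equal(distance_profile(y, rbind(x = x))$distance, d$distance[2])
  # euclidean alternative
  de <- distance_profile(x, pools, method = "euclidean")
  expect_equal(de$distance[2], sqrt(0.25 + 0.25))
  expect_error(distance_profile(c(A = 1, C = 0), pools), "mismatch")
})
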