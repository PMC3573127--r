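test_that("pairwise TMRCA under constant size matches the exponential
           closed form", {
  set.seed(101)
  ne <- 1000
  t2 <- replicate(2000, tmrca(simulate_genealogy(2, deme_spec("p", ne))))
  expect_lt(abs(mean(t2) - ne) / ne, 0.05)
  expect_gt(stats::ks.test(t2, stats::pexp, rate = 1 / ne)$p.value, 0.01)
})

test_that("total branch length for n = 10 matches the harmonic closed
           form", {
  set.seed(102)
  ne <- 800
  tb <- replicate(2000, total_branch_length(
    simulate_genealogy(10, deme_spec("p", ne))))
  expected <- ne * sum(2 / (1:9))
  se <- stats::sd(tb) / sqrt(length(tb))
  expect_lt(abs(mean(tb) - expected), 4 * se)
})

test_that("growth-model pairwise TMRCA matches the analytic time-rescaled
           distribution", {
  set.seed(103)
  d <- deme_spec("p", 2e5, anchor_ne = 5000, anchor_time = 1500)
  t2 <- replicate(2000, tmrca(simulate_genealogy(2, d)))
  r <- log(2e5 / 5000) / 1500
  expect_gt(stats::ks.test(t2, oracle_t2_cdf, ne0 = 2e5, r = r,
                           anchor = 1500)$p.value, 0.01)
})

test_that("heterochronous tips bound the TMRCA and enter at their age", {
  set.seed(104)
  sched <- tibble::tibble(deme = "p", age = c(0, 300), n = c(3, 2))
  for (i in 1:20) {
    g <- simulate_genealogy(sched, deme_spec("p", 500))
    expect_gte(tmrca(g), 300)
    expect_equal(sort(unique(g$tip_age)), c(0, 300))
  }
})

test_that("genealogy input validation", {
  expect_error(simulate_genealogy(2, deme_spec("p", -5)), "positive")
  expect_error(
    simulate_genealogy(tibble::tibble(deme = "q", age = 0, n = 2),
                       deme_spec("p", 100)), "unknown deme")
  # a sample scheduled in a deme after it has diverged away
  expect_error(simulate_genealogy(
    tibble::tibble(deme = c("a", "b"), age = c(0, 500), n = c(2, 2)),
    list(deme_spec("a", 100), deme_spec("b", 100)),
    events = list(divergence_event(200, of = "b", into = "a"))
  ), "diverged")
  # two demes, no merging event: cannot find a common ancestor
  expect_error(simulate_genealogy(
    tibble::tibble(deme = c("a", "b"), age = 0, n = c(2, 2)),
    list(deme_spec("a", 100), deme_spec("b", 100))
  ), "disconnected")
})

test_that("mutations follow the Poisson/finite-sites model", {
  d <- deme_spec("p", 1000)
  g <- simulate_genealogy(2, d, seed = 5)
  mm <- mutation_model()
  # zero rate: all haplotypes identical to the reference
  m0 <- mutate_sequences(g, mutation_model(mu = 0))
  expect_identical(unique(m0$key), "")
  # Poisson mean mu * L * total length on a fixed tree
  set.seed(105)
  nm <- replicate(400, attr(mutate_sequences(g, mm), "n_mutations"))
  expected <- mm$mu * mm$L * total_branch_length(g)
  expect_lt(abs(mean(nm) - expected),
            4 * sqrt(expected / length(nm)) + 1e-9)
  # realised transition fraction targets titv/(1+titv)
  set.seed(106)
  tot <- 0
  ti <- 0
  while (tot < 1e5) {
    m <- mutate_sequences(simulate_genealogy(25, deme_spec("p", 40000)), mm)
    tot <- tot + attr(m, "n_mutations")
    ti <- ti + attr(m, "n_transitions")
  }
  p <- mm$titv / (1 + mm$titv)
  expect_lt(abs(ti / tot - p), 4 * sqrt(p * (1 - p) / tot))
})

test_that("discrete gamma rate categories have mean one and match
           phangorn", {
  r <- discrete_gamma_rates(0.205, 10)
  expect_length(r, 10)
  expect_equal(mean(r), 1, tolerance = 1e-9)
  expect_true(all(diff(r) > 0))
  skip_if_not_installed("phangorn")
  expect_equal(sort(r), sort(phangorn::discrete.gamma(0.205, 10)),
               tolerance = 1e-6)
})

test_that("simulated datasets conserve tip counts, are deterministic under a
           seed, and keep diversities in range", {
  sched <- tibble::tibble(deme = "p", age = c(0, 140), n = c(30, 10),
                          group = c("mod", "anc"))
  d <- deme_spec("p", 5000)
  s1 <- simulate_dataset(sched, d, seed = 42)
  s2 <- simulate_dataset(sched, d, seed = 42)
  expect_identical(s1, s2)
  expect_named(s1, c("h_mod", "h_anc", "fst_mod_anc"))
  g <- simulate_genealogy(sched, d, seed = 42)
  expect_equal(g$n_tip, 40)
  expect_equal(sum(g$tip_group == "mod"), 30)
  set.seed(107)
  hs <- replicate(60, simulate_dataset(sched, d)[c("h_mod", "h_anc")])
  expect_true(all(hs >= 0 & hs <= 1))
})

test_that("two samples from one panmictic deme show no differentiation on
           average", {
  set.seed(108)
  sched <- tibble::tibble(deme = "p", age = 0, n = c(25, 25),
                          group = c("A", "B"))
  fst <- replicate(300, simulate_dataset(sched, deme_spec("p", 2000),
                                         model = mutation_model(mu = 3e-5)))
  f <- fst["fst_A_B", ]
  expect_lt(abs(mean(f)), 4 * stats::sd(f) / sqrt(length(f)) + 0.005)
})

test_that("a zero-fraction migration pulse is distributionally equivalent to
           the pulse-free model", {
  sched <- tibble::tibble(deme = c("a", "a", "b"), age = c(0, 140, 0),
                          n = c(25, 10, 25), group = c("A", "anc", "B"))
  demes <- list(deme_spec("a", 2e5, anchor_ne = 5000),
                deme_spec("b", 2e5, anchor_ne = 5000))
  ev_mig0 <- list(migration_pulse(50, sink = "a", source = "b", fraction = 0),
                  divergence_event(2000, of = "b", into = "a"))
  ev_none <- list(divergence_event(2000, of = "b", into = "a"))
  set.seed(109)
  s_mig0 <- replicate(250, simulate_dataset(sched, demes, ev_mig0)["fst_A_B"])
  s_none <- replicate(250, simulate_dataset(sched, demes, ev_none)["fst_A_B"])
  expect_gt(stats::ks.test(s_mig0, s_none)$p.value, 0.01)
})

test_that("genealogies convert to ape phylo objects", {
  skip_if_not_installed("ape")
  g <- simulate_genealogy(6, deme_spec("p", 300), seed = 11)
  tr <- as_phylo(g)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 6)
  expect_equal(max(ape::node.depth.edgelength(tr)), tmrca(g),
               tolerance = 1e-9)
})
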