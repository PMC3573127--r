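test_that("preset models encode the stated structures and priors", {
  m <- preset_models()
  expect_named(m, c("H0a", "H0b", "H0c", "H0d", "H0e",
                    "H1_uzpo_10", "H1_uzpo_50", "H1_uzpo_75",
                    "H1_boo_10", "H1_boo_50", "H1_boo_75"))
  h0a <- m$H0a
  expect_equal(h0a$k, 1L)
  expect_equal(h0a$priors$ne, c(1e5, 3e7))
  sched <- dplyr::summarise(dplyr::group_by(h0a$samples, .data$group),
                            n = sum(.data$n), age = .data$age[1])
  expect_equal(sched$n[sched$group == "NEE"], 621)
  expect_equal(sched$age[sched$group == "NEE"], 0)
  expect_equal(sched$n[sched$group == "aUzPo"], 11)
  expect_equal(sched$age[sched$group == "aUzPo"], 300)
  expect_equal(unname(h0a$observed),
               c(0.98, 0.74, 0.0538), tolerance = 1e-12)

  expect_equal(m$H0c$priors$ne, c(1e3, 5e5))
  h1 <- m$H1_uzpo_10
  expect_equal(h1$k, 4L)
  expect_equal(h1$priors$t_migration, c(2, 139))
  expect_equal(h1$priors$t_divergence, c(620, 2600))
  expect_equal(h1$priors$ne_sink, c(1e5, 1.5e7))
  expect_equal(h1$migrant_fraction, 0.10)
  expect_named(h1$observed, c("h_NEE", "h_CE", "h_aUzPo", "fst_NEE_CE",
                              "fst_NEE_aUzPo", "fst_CE_aUzPo"))
  expect_equal(unname(h1$observed),
               c(0.98, 0.97, 0.74, 0.0040, 0.0538, 0.6564))
  # pairs without a reported fixture value (e.g. saa-CE) are excluded
  expect_false("fst_saa_CE" %in% names(m$H0c$observed))
  # aHG tips spread evenly over the reported age range
  hg_ages <- m$H0d$samples$age[m$H0d$samples$group == "aHG"]
  expect_equal(hg_ages, seq(168, 614, length.out = 20))
})

test_that("every H0 deme trajectory passes through the ancestral size 5000
           at 1500 generations", {
  m <- preset_models()
  for (name in c("H0a", "H0b", "H0c", "H0d", "H0e")) {
    model <- m[[name]]
    for (ne in c(model$priors$ne[1], exp(mean(log(model$priors$ne))),
                 model$priors$ne[2])) {
      inst <- mtabc:::instantiate_model(model, c(ne = ne))
      expect_equal(inst$deme$ne0 * exp(-inst$deme$growth * 1500), 5000,
                   tolerance = 1e-9)
    }
  }
  inst1 <- mtabc:::instantiate_model(
    m$H1_uzpo_10, c(ne_sink = 1e6, ne_source = 2e6, t_migration = 50,
                    t_divergence = 1000))
  expect_equal(inst1$deme$ne0 * exp(-inst1$deme$growth * 1500),
               c(5000, 5000), tolerance = 1e-9)
})

test_that("prior draws stay inside their bounds", {
  m <- preset_models()$H1_uzpo_10
  set.seed(201)
  for (i in 1:50) {
    p <- draw_model_params(m)
    for (nm in names(m$priors)) {
      expect_gte(p[[nm]], m$priors[[nm]][1])
      expect_lte(p[[nm]], m$priors[[nm]][2])
    }
  }
})

test_that("the rejection step retains ceil(fraction * n) closest draws and
           records the tolerance", {
  set.seed(202)
  n <- 500
  sims <- list(params = tibble::tibble(theta = runif(n)),
               stats = cbind(s1 = rnorm(n), s2 = rnorm(n, sd = 5)))
  obs <- c(s1 = 0, s2 = 0)
  rej <- abc_reject(obs, sims, fraction = 0.01)
  expect_equal(nrow(rej$retained), ceiling(0.01 * n))
  expect_equal(rej$tolerance, max(rej$retained$distance))
  # retained distances are the smallest ones
  sds <- apply(sims$stats, 2, sd)
  d <- sqrt(rowSums(sweep(sims$stats, 2, sds, "/")^2))
  expect_equal(sort(rej$retained$distance), sort(d)[1:5], tolerance = 1e-12)
  # an exact hit is always retained
  sims$stats[7, ] <- obs
  rej2 <- abc_reject(obs, sims, fraction = 0.01)
  expect_true(any(abs(rej2$retained$distance) < 1e-12))
  expect_error(abc_reject(c(bad = 1), sims), "match")
  sims$stats[, 2] <- 1
  expect_warning(abc_reject(obs, sims), "zero-variance")
})

test_that("posterior point estimates behave on degenerate and uniform
           draws and stay inside the prior", {
  const <- tibble::tibble(a = rep(3.5, 40), distance = 0)
  expect_equal(estimate_posterior(const)[["a"]], 3.5)
  set.seed(203)
  unif <- tibble::tibble(a = runif(1e4), distance = 0)
  expect_lt(abs(estimate_posterior(unif)[["a"]] - 0.5), 0.02)
  expect_true(estimate_posterior(unif, method = "mode")[["a"]] >= 0 &&
                estimate_posterior(unif, method = "mode")[["a"]] <= 1)
  expect_error(estimate_posterior(unif[0, ]), "retained")
})

test_that("the simulation-based AIC applies the likelihood floor and the
           parameter penalty", {
  model <- preset_models()$H0a
  fake_rej <- structure(list(
    observed = model$observed,
    stat_sd = stats::setNames(rep(1, 3), names(model$observed)),
    tolerance = Inf, fraction = 0.01, n_sims = 100,
    retained = tibble::tibble(ne = 2e5, distance = 0)
  ), class = "mt_abc_rejection")
  fit_all <- model_fit(model, c(ne = 2e5), fake_rej, n_final = 100)
  expect_equal(fit_all$likelihood, 1)
  expect_equal(fit_all$aic, 2)               # -2 log 1 + 2k, k = 1
  fake_rej$tolerance <- -1                   # nothing can fall inside
  fit_none <- model_fit(model, c(ne = 2e5), fake_rej, n_final = 100)
  expect_equal(fit_none$likelihood, 1 / 101)
  expect_equal(fit_none$aic, -2 * log(1 / 101) + 2)
  expect_error(model_fit(model, c(ne = 2e5), fake_rej, n_final = 50),
               "at least 100")
})

test_that("Akaike weights: closed forms, normalisation, shift invariance", {
  expect_equal(akaike_weights(c(4, 4)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(exp(0), exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  set.seed(204)
  aics <- runif(5, 10, 40)
  w1 <- akaike_weights(aics)
  w2 <- akaike_weights(aics + 123.4)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_equal(order(w1), order(w2))
  expect_error(akaike_weights(numeric(0)), "AIC")
})

test_that("comparing a model against itself gives weights near one half and
           seeded runs are reproducible", {
  m <- preset_models()$H0a
  m2 <- m
  m2$name <- "H0a_copy"
  res <- suppressWarnings(
    run_model_comparison(list(m, m2), n_sims = 400, n_final = 150,
                         seed = 205))
  expect_equal(sum(res$akaike_weight), 1, tolerance = 1e-12)
  expect_lt(abs(res$akaike_weight[1] - 0.5), 0.35)
  res_b <- suppressWarnings(
    run_model_comparison(list(m, m2), n_sims = 400, n_final = 150,
                         seed = 205))
  expect_identical(res$aic, res_b$aic)
  expect_identical(res$model, res_b$model)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_models, 2)
})
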