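test_that("Yule simulator produces seeded, ultrametric trees", {
  cherry <- simulate_yule_tree(2, birth = 1, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  d <- unname(diag(phylo_covariance(cherry)))
  expect_equal(d[1], d[2], tolerance = 1e-12)

  t1 <- simulate_yule_tree(50, birth = 0.3, seed = 99)
  t2 <- simulate_yule_tree(50, birth = 0.3, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulate_yule_tree(50, 0.3, seed = 100))))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_yule_tree(1, 1, seed = 1), "n_tips")
  expect_error(simulate_yule_tree(5, 1), "seed")
})

test_that("mean tree depth matches the analytic pure-birth expectation", {
  n <- 10; rate <- 1
  depths <- vapply(1:500, function(s) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, rate, seed = s)))
  }, numeric(1))
  expected <- sum(1 / (rate * (2:n)))
  expect_lt(abs(mean(depths) - expected) / expected, 0.1)
})

test_that("trait simulation honors the noiseless and independent limits", {
  tr <- simulate_yule_tree(40, birth = 0.5, seed = 7)
  # sigma2 = 0: exact line, PGLS recovers truth
  d0 <- simulate_allometric_traits(tr, slope = 0.933, intercept = 0.088,
                                   sigma2 = 0, lambda = 1, seed = 8)
  f0 <- fit_pgls(d0, tr, lambda = 1)
  expect_equal(f0$slope, 0.933, tolerance = 1e-8)
  expect_equal(f0$intercept, 0.088, tolerance = 1e-8)

  # lambda = 0: residuals uncorrelated across sister tips
  resids <- sapply(1:60, function(s) {
    d <- simulate_allometric_traits(tr, slope = 1, intercept = 0,
                                    sigma2 = 0.5, lambda = 0, seed = 100 + s)
    log10(d$y) - 1 * log10(d$x)
  })
  # correlation between the residuals of two fixed tips across replicates
  r <- cor(resids[1, ], resids[2, ])
  expect_lt(abs(r), 0.35)

  # determinism
  expect_identical(
    simulate_allometric_traits(tr, seed = 5),
    simulate_allometric_traits(tr, seed = 5)
  )
})

test_that("specimen tables expand species with noise and maturity flags", {
  tr <- simulate_yule_tree(10, birth = 0.5, seed = 11)
  spec0 <- simulation_spec(n_tips = 10, replicates = 1, cv = 0,
                           subadult_fraction = 0, seed = 12)
  tab0 <- simulate_specimen_table(tr, spec0)
  sp <- simulate_allometric_traits(tr, slope = spec0$slope,
                                   intercept = spec0$intercept,
                                   sigma2 = spec0$sigma2,
                                   lambda = spec0$lambda,
                                   x_mean = spec0$x_mean, x_sd = spec0$x_sd,
                                   seed = 12)
  # cv = 0, one replicate: specimen values equal species values
  expect_equal(sort(tab0$ocw_mm), sort(sp$x), tolerance = 1e-12)
  expect_true(all(tab0$maturity == "adult"))

  # subadult fraction materializes at the expected rate (~112 -> ~74 adults)
  spec1 <- simulation_spec(n_tips = 35, replicates = 3.2,
                           subadult_fraction = 0.34, seed = 13)
  tr35 <- simulate_yule_tree(35, birth = 0.1, seed = 13)
  tab1 <- simulate_specimen_table(tr35, spec1)
  frac_adult <- mean(tab1$maturity == "adult")
  se <- sqrt(0.34 * 0.66 / nrow(tab1))
  expect_lt(abs(frac_adult - 0.66), 4 * se)

  # aggregation row count equals species with >= 1 adult record
  m <- suppressWarnings(
    aggregate_species_means(tab1, c("ocw_mm", "body_mass_kg")))
  expect_equal(nrow(m),
               dplyr::n_distinct(tab1$taxon[tab1$maturity == "adult"]))

  expect_error(simulation_spec(n_tips = 10), "seed")
})

test_that("end-to-end synthetic recovery: aggregate, fit, predict", {
  spec <- simulation_spec(n_tips = 35, birth = 0.1, slope = 3.1,
                          intercept = -3.5, sigma2 = 0.005, lambda = 0.9,
                          cv = 0.08, seed = 17)
  tr <- simulate_yule_tree(spec$n_tips, spec$birth, seed = 17)
  tab <- simulate_specimen_table(tr, spec)
  means <- suppressWarnings(
    aggregate_species_means(tab, c("ocw_mm", "body_mass_kg")))
  traits <- tibble::tibble(taxon = means$taxon, x = means$ocw_mm,
                           y = means$body_mass_kg)
  fit <- fit_pgls(traits, tr)
  truth <- simulate_allometric_traits(tr, slope = spec$slope,
                                      intercept = spec$intercept,
                                      sigma2 = spec$sigma2,
                                      lambda = spec$lambda,
                                      x_mean = spec$x_mean,
                                      x_sd = spec$x_sd, seed = 17)
  pred <- predict_body_mass_from_ocw(truth$x, fit)
  med_rel_err <- stats::median(abs(pred - truth$y) / truth$y)
  expect_lt(med_rel_err, 2 * spec$cv)
})
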