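test_that("GLS recovers a perfect line regardless of covariance", {
  d3 <- tibble::tibble(taxon = c("A", "B", "C"), x = c(1, 2, 3), y = c(1, 2, 3))
  f_id <- fit_gls(d3, diag(3) |> `dimnames<-`(list(c("A", "B", "C"),
                                                   c("A", "B", "C"))),
                  log10_transform = FALSE)
  expect_equal(f_id$slope, 1, tolerance = 1e-12)
  expect_equal(f_id$intercept, 0, tolerance = 1e-12)

  tr3 <- toy_tree_3()
  dperf <- tibble::tibble(taxon = c("A", "B", "C"),
                          x = c(10, 100, 1000), y = c(10, 100, 1000))
  f_tree <- fit_gls(dperf, phylo_covariance(tr3))
  expect_equal(f_tree$slope, 1, tolerance = 1e-10)
  expect_equal(f_tree$intercept, 0, tolerance = 1e-10)
})

test_that("GLS matches a brute-force normal-equation oracle on a 4-taxon toy", {
  tr <- toy_tree_4()
  d <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                      x = c(1.2, 3.4, 0.8, 2.2), y = c(2.0, 5.5, 1.4, 4.1))
  V <- phylo_covariance(tr, lambda = 0.7)
  fit <- fit_gls(d, V, log10_transform = FALSE, lambda = 0.7)
  b_oracle <- gls_bruteforce(cbind(1, d$x), d$y, V[d$taxon, d$taxon])
  expect_equal(fit$intercept, b_oracle[1], tolerance = 1e-10)
  expect_equal(fit$slope, b_oracle[2], tolerance = 1e-10)
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  withr::with_seed(7, {
    n <- 12
    d <- tibble::tibble(taxon = paste0("t", 1:n),
                        x = 10^runif(n, 0, 2), y = 10^runif(n, 0, 3))
  })
  V <- diag(n); dimnames(V) <- list(d$taxon, d$taxon)
  f_gls <- fit_gls(d, V)
  f_lm <- lm(log10(y) ~ log10(x), data = d)
  expect_equal(f_gls$slope, unname(coef(f_lm)[2]), tolerance = 1e-10)
  expect_equal(f_gls$intercept, unname(coef(f_lm)[1]), tolerance = 1e-10)
  expect_equal(f_gls$slope_se, summary(f_lm)$coefficients[2, 2],
               tolerance = 1e-10)
  expect_equal(f_gls$adj_r2, summary(f_lm)$adj.r.squared, tolerance = 1e-10)
})

test_that("mismatched taxa and rank deficiency raise explicit errors", {
  d <- tibble::tibble(taxon = c("A", "B", "C"), x = 1:3, y = 1:3)
  V <- diag(3); dimnames(V) <- list(c("A", "B", "Z"), c("A", "B", "Z"))
  expect_error(fit_gls(d, V, log10_transform = FALSE), "do not match")
  Vok <- diag(3); dimnames(Vok) <- list(c("A", "B", "C"), c("A", "B", "C"))
  dconst <- tibble::tibble(taxon = c("A", "B", "C"), x = c(2, 2, 2), y = 1:3)
  expect_error(fit_gls(dconst, Vok, log10_transform = FALSE),
               "rank-deficient")
})

test_that("PGLS with ML lambda equals OLS on a star phylogeny", {
  st <- star_tree(10)
  withr::with_seed(11, {
    d <- tibble::tibble(taxon = st$tip.label,
                        x = 10^runif(10, 1, 3), y = 10^rnorm(10, 2, 0.5))
  })
  f_star <- fit_pgls(d, st)
  f_ols <- fit_ols_loglog(d)
  expect_equal(f_star$slope, f_ols$slope, tolerance = 1e-8)
  expect_equal(f_star$intercept, f_ols$intercept, tolerance = 1e-8)
})

test_that("profile likelihood at the ML lambda dominates the grid", {
  tr <- simulate_yule_tree(30, birth = 0.5, seed = 5)
  d <- simulate_allometric_traits(tr, slope = 0.9, intercept = 0.1,
                                  sigma2 = 0.05, lambda = 0.6, seed = 6)
  fit <- fit_pgls(d, tr)
  prof <- lambda_profile(d, tr, lambdas = seq(0, 1, length.out = 101))
  expect_gte(fit$log_likelihood, max(prof$log_likelihood) - 1e-9)
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
})

test_that("fixed-lambda PGLS agrees with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(25, birth = 0.5, seed = 9)
  d <- simulate_allometric_traits(tr, slope = 0.93, intercept = 0.09,
                                  sigma2 = 0.02, lambda = 0.8, seed = 10)
  for (lam in c(0.3, 0.8, 1)) {
    mine <- fit_pgls(d, tr, lambda = lam)
    df <- data.frame(lx = log10(d$x), ly = log10(d$y), row.names = d$taxon)
    # corPagel warns that it takes species in data order; `df` is built in
    # tip order, which is what we want
    ref <- suppressWarnings(
      nlme::gls(ly ~ lx, data = df,
                correlation = ape::corPagel(lam, tr, fixed = TRUE,
                                            form = ~ 1)))
    # corPagel orders by the data rows; align by taxon via form default
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  }
})

test_that("log-likelihood is invariant to uniform branch rescaling", {
  tr <- simulate_yule_tree(20, birth = 1, seed = 13)
  d <- simulate_allometric_traits(tr, slope = 1.5, intercept = 0,
                                  sigma2 = 0.03, lambda = 0.5, seed = 14)
  f1 <- fit_pgls(d, tr, lambda = 0.5)
  tr_scaled <- tr
  tr_scaled$edge.length <- tr$edge.length * 37.5
  f2 <- fit_pgls(d, tr_scaled, lambda = 0.5)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
})

test_that("OLS on log10 data nails exact power laws and degenerate cases", {
  d <- tibble::tibble(x = c(1, 10, 100), y = 2 * c(1, 10, 100)^3)
  f <- fit_ols_loglog(d)
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, log10(2), tolerance = 1e-12)

  dconst <- tibble::tibble(x = c(1, 10, 100), y = c(5, 5, 5))
  expect_equal(fit_ols_loglog(dconst)$slope, 0, tolerance = 1e-12)

  withr::with_seed(3, {
    dr <- tibble::tibble(x = 10^runif(10, 0, 2), y = 10^runif(10, 0, 2))
  })
  fr <- fit_ols_loglog(dr)
  b <- gls_bruteforce(cbind(1, log10(dr$x)), log10(dr$y), diag(10))
  expect_equal(unname(coef(fr)), unname(b), tolerance = 1e-10)

  expect_error(fit_ols_loglog(dr[1:2, ]), ">= 3")
  expect_error(fit_ols_loglog(tibble::tibble(x = c(1, -1, 2), y = c(1, 2, 3))),
               "positive")
})

test_that("species means are computed on adults, natural scale", {
  rec <- tibble::tibble(
    taxon = c("Aa", "Aa", "Aa", "Bb", "Bb", "Cc"),
    maturity = c("adult", "adult", "subadult", "adult", "unknown", "subadult"),
    ocw_mm = c(100, 200, 50, 80, 90, 60),
    body_mass_kg = c(10, 20, 2, NA, 9, 5)
  )
  expect_warning(
    m <- aggregate_species_means(rec, c("ocw_mm", "body_mass_kg")),
    "omitted"
  )
  expect_equal(nrow(m), 1)  # only Aa has complete adult records
  expect_equal(m$ocw_mm, 150)        # arithmetic mean, subadult excluded
  expect_equal(m$body_mass_kg, 15)
  dropped <- attr(m, "dropped")
  expect_equal(dropped$n[dropped$reason == "not_adult"], 3)
  expect_equal(dropped$n[dropped$reason == "incomplete"], 1)

  # adults_only = FALSE brings the other species in
  m_all <- aggregate_species_means(rec, "ocw_mm", adults_only = FALSE)
  expect_equal(nrow(m_all), 3)

  # geometric switch averages on log scale
  rec2 <- tibble::tibble(taxon = c("Aa", "Aa"), maturity = "adult",
                         ocw_mm = c(10, 1000))
  expect_equal(aggregate_species_means(rec2, "ocw_mm",
                                       geometric = TRUE)$ocw_mm, 100)
})
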