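test_that("one-way ANOVA matches a hand sums-of-squares oracle and base aov", {
  withr::with_seed(41, {
    g <- list(a = rnorm(4), b = rnorm(4, 0.5), c = rnorm(4, 1))
  })
  res <- one_way_anova(g)
  # brute-force decomposition
  allv <- unlist(g)
  grand <- mean(allv)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  # independent route through base aov
  df <- data.frame(v = allv, grp = rep(names(g), lengths(g)))
  av <- summary(stats::aov(v ~ grp, data = df))[[1]]
  expect_equal(res$statistic, av$`F value`[1], tolerance = 1e-8)
  expect_equal(res$p.value, av$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("ANOVA degenerate cases behave as defined", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$p.value, 1)
  expect_warning(sep <- one_way_anova(list(c(0, 0), c(1, 1))), "separation")
  expect_equal(sep$p.value, 0)
  expect_true(sep$exact.separation)
  expect_error(one_way_anova(list(c(1, 2))), ">= 2 groups")
  expect_error(one_way_anova(list(1, 2)), "degrees of freedom")
})

test_that("studentized-range CDF agrees with the base R implementation", {
  for (k in c(2, 3, 5)) {
    for (df in c(4, 10, 60)) {
      q <- c(0.5, 2, 3.5, 5)
      expect_equal(studentized_range_cdf(q, k, df),
                   stats::ptukey(q, k, df), tolerance = 1e-6)
    }
  }
  expect_equal(studentized_range_cdf(3, 4, Inf), stats::ptukey(3, 4, Inf),
               tolerance = 1e-6)
  expect_equal(studentized_range_cdf(0, 3, 10), 0)
})

test_that("Tukey with two groups reduces to the pooled t-test", {
  withr::with_seed(43, {
    g <- list(x = rnorm(6), y = rnorm(7, 0.8))
  })
  tk <- tukey_hsd(g)
  tt <- t.test(g$y, g$x, var.equal = TRUE)
  expect_equal(tk$statistic, sqrt(2) * abs(tt$statistic[[1]]),
               tolerance = 1e-10)
  expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-4)
})

test_that("Tukey-Kramer matches base TukeyHSD on unequal groups", {
  withr::with_seed(44, {
    g <- list(a = rnorm(3), b = rnorm(3, 1), c = rnorm(4, 0.3))
  })
  tk <- tukey_hsd(g)
  df <- data.frame(v = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- as.data.frame(stats::TukeyHSD(stats::aov(v ~ grp, data = df))$grp)
  # base labels pairs "b-a", "c-a", "c-b"; ours are (a,b), (a,c), (b,c)
  expect_equal(tk$estimate, ref$diff, tolerance = 1e-10)
  expect_equal(tk$adj.p.value, ref$`p adj`, tolerance = 1e-6)
})

test_that("identical groups give adjusted p of 1 and zero estimates", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  tk <- tukey_hsd(g)
  expect_equal(tk$adj.p.value, rep(1, 3))
  expect_equal(tk$estimate, rep(0, 3))
})

test_that("Tukey adjustment is conservative relative to pairwise t-tests", {
  withr::with_seed(45, {
    for (rep in 1:5) {
      g <- list(a = rnorm(5), b = rnorm(5, 0.5), c = rnorm(6, 1),
                d = rnorm(4, 0.2))
      tk <- tukey_hsd(g)
      df_w <- sum(lengths(g)) - length(g)
      # unadjusted pairwise p from the same pooled SE and df
      p_unadj <- 2 * stats::pt(-tk$statistic / sqrt(2), df_w)
      expect_true(all(tk$adj.p.value >= p_unadj - 1e-9))
    }
  })
})

test_that("statistics are invariant to group and value permutation", {
  withr::with_seed(46, {
    g <- list(a = rnorm(4), b = rnorm(5, 1), c = rnorm(3))
  })
  perm <- list(c = rev(g$c), a = g$a[c(3, 1, 2, 4)], b = g$b)
  expect_equal(one_way_anova(g)$statistic, one_way_anova(perm)$statistic,
               tolerance = 1e-12)
  tk1 <- tukey_hsd(g)
  tk2 <- tukey_hsd(perm)
  key <- function(t) paste(pmin(t$group1, t$group2), pmax(t$group1, t$group2))
  expect_equal(tk1$adj.p.value[order(key(tk1))],
               tk2$adj.p.value[order(key(tk2))], tolerance = 1e-12)
})

test_that("time-bin assignment groups species as published", {
  est <- build_fossil_estimates(eocene_archaeocetes())
  sp <- assign_time_bins(est)
  mid <- sp$taxon[sp$bin == "middle Eocene archaeocetes"]
  expect_setequal(mid, c("Rodhocetus_kasrani", "Dalanistes_ahmedi",
                         "Remingtonocetus_harudiensis"))
  bas <- sp[sp$bin == "late Eocene basilosaurids", ]
  expect_equal(nrow(bas), 3)  # 3 species from 4 specimens
  expect_equal(bas$n_specimens[bas$taxon == "Zygorhiza_kochii"], 2)
  # the Zygorhiza value is the mean of its two specimens' log10 EQ
  zk <- est[est$taxon == "Zygorhiza_kochii", ]
  expect_equal(bas$value[bas$taxon == "Zygorhiza_kochii"],
               mean(zk$log10_EQ_0.56), tolerance = 1e-12)
  # empty input gives empty groups
  expect_equal(nrow(assign_time_bins(est[0, ])), 0)
  # an estimate matching no bin is excluded with a warning
  odd <- est[1, ]
  odd$family <- "Pakicetidae"
  odd$age_ma <- 55
  expect_warning(assign_time_bins(dplyr::bind_rows(est, odd)), "no bin")
})

test_that("epoch comparison composes ANOVA and Tukey over bins", {
  est <- build_fossil_estimates(eocene_archaeocetes())
  cmp <- compare_epochs(est)
  expect_s3_class(cmp, "epoch_comparison")
  expect_equal(glance(cmp)$k, 2)
  expect_true(all(tidy(cmp)$adj.p.value >= 0 & tidy(cmp)$adj.p.value <= 1))
  # middle Eocene mean log10 EQ is lower than late Eocene basilosaurids
  means <- tapply(cmp$groups$value, cmp$groups$bin, mean)
  expect_lt(means["middle Eocene archaeocetes"],
            means["late Eocene basilosaurids"])
})
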