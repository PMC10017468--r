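test_that("identical group distributions give null statistics", {
  d <- data.frame(group = rep(c("a", "b"), each = 6),
                  y = rep(c(1, 2, 3), 4),
                  cat = rep(c("x", "y"), 6))
  chi <- compare_groups(d, "cat", "chi_square")
  expect_equal(unname(chi$statistic), 0)
  expect_equal(chi$p_value, 1)
  an <- compare_groups(d, "y", "anova")
  expect_equal(unname(an$statistic), 0)
  expect_equal(an$p_value, 1)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(17)
  for (i in 1:5) {
    d <- data.frame(group = rep(c("a", "b"), c(8, 13)),
                    y = c(rnorm(8, 0), rnorm(13, 0.8)))
    f <- compare_groups(d, "y", "anova")$statistic
    t <- t.test(y ~ group, data = d, var.equal = TRUE)$statistic
    expect_equal(unname(f), unname(t^2), tolerance = 1e-10)
  }
})

test_that("Mann-Whitney on fully separated triples gives exact p = 0.05", {
  d <- data.frame(group = rep(c("lo", "hi"), each = 3),
                  y = c(1, 2, 3, 4, 5, 6))
  # group factor orders hi < lo; 'hi' values all larger
  mw <- compare_groups(d, "y", "mann_whitney", alternative = "greater")
  expect_equal(mw$p_value, 0.05)   # 1 / choose(6, 3)
  expect_equal(unname(mw$statistic), 9)  # all 9 pairs favor 'hi'
  expect_error(compare_groups(data.frame(group = c("a", "a", "b", "b", "c", "c"),
                                         y = 1:6),
                              "y", "mann_whitney"), "exactly 2")
})

test_that("ANCOVA group F matches an explicit normal-equations solve", {
  fx <- staged_fixture()
  d <- fx$data
  res <- compare_groups(d, "svlt", "ancova_age")
  expect_lt(res$p_value, 0.01)

  # oracle: least squares via the normal equations, F from nested RSS
  g <- droplevels(factor(d$group))
  X1 <- cbind(1, d$age, stats::model.matrix(~ g)[, -1])
  X0 <- cbind(1, d$age)
  rss <- function(X, y) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  y <- d$svlt
  r1 <- rss(X1, y)
  r0 <- rss(X0, y)
  df1 <- nlevels(g) - 1
  df2 <- nrow(X1) - ncol(X1)
  f_oracle <- ((r0 - r1) / df1) / (r1 / df2)
  expect_equal(unname(res$statistic), f_oracle, tolerance = 1e-8)
})

test_that("Tukey post hoc covers all pairs and matches TukeyHSD without covariates", {
  set.seed(4)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 12),
                  age = rnorm(36, 70, 6),
                  y = rnorm(36, rep(c(0, 0.5, 1.2), each = 12)))
  res <- compare_groups(d, "y", "tukey_posthoc")
  expect_equal(nrow(res$pairwise), 3)
  ref <- TukeyHSD(aov(y ~ group, data = d))$group
  expect_equal(unname(sort(res$pairwise$p.value)),
               sort(unname(ref[, "p adj"])))

  # with a covariate the contrasts are between adjusted means
  res_adj <- compare_groups(d, "y", "tukey_posthoc", covariates = "age")
  expect_equal(nrow(res_adj$pairwise), 3)
  expect_true(all(res_adj$pairwise$p.value >= 0 &
                    res_adj$pairwise$p.value <= 1))
  td <- tidy(res_adj)
  expect_equal(nrow(td), 3)
})

test_that("Jonckheere statistic and permutation p are exact on singletons", {
  res <- jonckheere_trend(list(1, 2, 3), alternative = "increasing",
                          n_perm = 6000, seed = 99)
  expect_equal(unname(res$statistic), 3)  # maximal: every pair concordant
  expect_equal(res$details$perm_p, 1 / 6, tolerance = 0.02)
})

test_that("fully tied data give the null JT value with p = 1", {
  res <- jonckheere_trend(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(unname(res$statistic), res$details$null_mean)
  expect_equal(res$p_value, 1)
})

test_that("normal-approximation and permutation p agree on small samples", {
  set.seed(31)
  for (i in 1:4) {
    samples <- lapply(c(0, 0.4, 0.9), function(m) rnorm(12, m))
    approx <- jonckheere_trend(samples, alternative = "increasing")
    perm <- jonckheere_trend(samples, alternative = "increasing",
                             n_perm = 4000, seed = 7 + i)
    expect_lt(abs(approx$p_value - perm$details$perm_p), 0.02)
  }
  # with heavy ties
  samples <- lapply(c(0, 0.5, 1), function(m) round(rnorm(10, m)))
  approx <- jonckheere_trend(samples, alternative = "increasing")
  perm <- jonckheere_trend(samples, alternative = "increasing",
                           n_perm = 4000, seed = 77)
  expect_lt(abs(approx$p_value - perm$details$perm_p), 0.02)
  expect_error(jonckheere_trend(list(1:3, 4:6)), "at least 3")
})

test_that("bootstrap frequencies behave at the degenerate extremes", {
  m <- matrix(1.0, nrow = 40, ncol = 10)
  colnames(m) <- region_names()
  m[, c("parietal_left", "parietal_right")] <- 2.0  # A in everyone
  cuts <- unit_cutoffs(level = 1.5)
  st <- stage_cohort(profiles_from_matrix(m),
                     cuts, ligand_calibration("FBB", 1.0, 2.0),
                     threshold = global_threshold(1000))
  fb <- involvement_frequency_bootstrap(st, n_resamples = 500, seed = 5)
  f <- setNames(fb$frequencies$frequency, fb$frequencies$lobe)
  expect_equal(unname(f["parietal"]), 1)
  expect_equal(unname(f["striatum"]), 0)
  ps <- fb$pairwise[fb$pairwise$lobe_a == "parietal" &
                      fb$pairwise$lobe_b == "striatum", ]
  expect_equal(ps$neg_log10_p, -log10(1 / 500))

  # identical flags in two lobes -> p near 1
  m2 <- matrix(1.0, nrow = 60, ncol = 10)
  colnames(m2) <- region_names()
  inv <- runif(60) < 0.4
  m2[inv, c("parietal_left", "frontal_left")] <- 2.0
  st2 <- stage_cohort(profiles_from_matrix(m2), cuts,
                      ligand_calibration("FBB", 1.0, 2.0),
                      threshold = global_threshold(1000))
  fb2 <- involvement_frequency_bootstrap(st2, n_resamples = 500, seed = 6)
  pf <- fb2$pairwise[fb2$pairwise$lobe_a == "frontal" &
                       fb2$pairwise$lobe_b == "parietal", ]
  expect_gt(pf$p_value, 0.9)

  empty <- st[st$n_involved == 0, ]
  expect_error(involvement_frequency_bootstrap(empty, 500, seed = 1),
               "no participants")
})

test_that("bootstrap means match point frequencies within Monte-Carlo error", {
  fx <- staged_fixture()
  fb <- involvement_frequency_bootstrap(fx$staged, n_resamples = 1000,
                                        seed = 11)
  f <- fb$frequencies
  mc_se <- f$boot_sd / sqrt(fb$n_resamples)
  expect_true(all(abs(f$boot_mean - f$frequency) <= 2 * mc_se + 1e-9))
  # resampling is reproducible under the same seed
  fb2 <- involvement_frequency_bootstrap(fx$staged, n_resamples = 1000,
                                         seed = 11)
  expect_identical(fb$pairwise, fb2$pairwise)
})

test_that("AIC comparison prefers the grouping that generated the outcome", {
  fx <- staged_fixture()
  d <- fx$data
  # planted outcomes follow the F/G groups
  for (oc in c("svlt", "hv")) {
    cmp <- compare_groupings_aic(d, oc)
    expect_equal(cmp$preferred, "fg")
    expect_lt(cmp$aic_fg, cmp$aic_cl)
  }
  # identical groupings tie, broken toward fg
  d2 <- d
  d2$global_cl <- (as.integer(d2$group) - 1) * 20  # bands reproduce groups
  cmp2 <- compare_groupings_aic(d2, "svlt")
  expect_equal(cmp2$aic_fg, cmp2$aic_cl)
  expect_equal(cmp2$preferred, "fg")
  expect_error(compare_groupings_aic(dplyr::mutate(d, global_cl = 0),
                                     "svlt"), "degenerate")
})

test_that("group comparisons validate their inputs", {
  d <- data.frame(group = rep("a", 10), y = rnorm(10))
  expect_error(compare_groups(d, "y", "anova"), "2 non-empty groups")
  d2 <- data.frame(group = rep(c("a", "b"), each = 5), y = rep(1, 10))
  expect_error(compare_groups(d2, "y", "anova"), "zero variance")
  expect_error(compare_groups(d2, "y", "ancova_age", covariates = "nope"),
               "not in data")
})
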