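test_that("Welch ANOVA matches a step-by-step evaluation of the formula", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  res <- welch_anova(groups)

  # independent hand evaluation
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, var, 0)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  k <- 3
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  f_hand <- (sum(w * (m - mw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2_hand <- (k^2 - 1) / (3 * lam)
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)
  expect_equal(res$df2, df2_hand, tolerance = 1e-10)
  expect_equal(res$p.value, pf(f_hand, 2, df2_hand, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Welch ANOVA agrees with oneway.test and degenerates correctly", {
  set.seed(5)
  x <- rnorm(60, rep(c(0, 0.5, 2), each = 20), rep(c(1, 2, 0.5), each = 20))
  g <- rep(1:3, each = 20)
  res <- welch_anova(x, g)
  ref <- oneway.test(x ~ g)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df2, unname(ref$parameter[2]), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)

  # equal group means -> F = 0, p = 1
  eq <- welch_anova(list(c(-1, 0, 1), c(-2, 0, 2), c(-3, 0, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "zero-variance")
  expect_error(welch_anova(list(c(1, 2, 3))), "at least 2 groups")
  expect_error(welch_anova(list(c(1, 2, 3), 5)), "at least 2 observations")
})

test_that("Welch ANOVA reduces to the squared Welch t at k = 2", {
  set.seed(9)
  a <- rnorm(12, 0, 1)
  b <- rnorm(7, 1, 3)
  res <- welch_anova(list(a, b))
  tt <- t.test(a, b)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$df2, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("Welch ANOVA relates exactly to classical ANOVA when balanced
          and homoscedastic", {
  # with equal variances and equal n the Welch numerator IS the classical
  # F; the full statistic differs by the small-sample correction factor
  # 1 + 2(k-2)/(k^2-1) * Lambda (stats::oneway.test behaves identically),
  # and converges to the classical F as n grows
  s <- data.frame(n = c(8, 8, 8), mean = c(1, 2, 5), var = c(2, 2, 2))
  res <- welch_anova(s)
  f_classic <- (8 * sum((s$mean - mean(s$mean))^2) / 2) / 2
  k <- 3
  lam <- k * (1 - 1 / k)^2 / (s$n[1] - 1)  # Lambda with equal weights
  corr <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  expect_equal(res$statistic * corr, f_classic, tolerance = 1e-10)

  big <- data.frame(n = rep(1e7, 3), mean = c(1, 2, 5), var = c(2, 2, 2))
  f_big <- (1e7 * sum((big$mean - mean(big$mean))^2) / 2) / 2
  expect_equal(welch_anova(big)$statistic / f_big, 1, tolerance = 1e-6)
})

test_that("the studentized range CDF obeys its limits and identities", {
  expect_equal(studentized_range_cdf(0, 3, 10), 0)
  expect_gt(studentized_range_cdf(50, 3, 10), 1 - 1e-6)

  # k = 2 identity: P(Q <= q) = P(|t_df| <= q / sqrt(2))
  for (df in c(3, 10, 40)) {
    q <- c(0.5, 1, 2, 3.5, 5)
    own <- studentized_range_cdf(q, 2, df)
    ident <- 2 * pt(q / sqrt(2), df) - 1
    expect_equal(own, ident, tolerance = 1e-6)
  }

  # monotone in q, non-increasing in k
  qs <- seq(0.5, 6, by = 0.5)
  vals <- studentized_range_cdf(qs, 4, 12)
  expect_true(all(diff(vals) > 0))
  expect_true(all(studentized_range_cdf(qs, 5, 12) <= vals + 1e-9))

  expect_error(studentized_range_cdf(-1, 3, 10), "non-negative")
  expect_error(studentized_range_cdf(1, 1, 10), "k")
  expect_error(studentized_range_cdf(1, 3, 0), "df")
})

test_that("the studentized range CDF matches the reference implementation", {
  grid <- expand.grid(q = c(0.8, 2, 3.5, 5), k = c(2, 3, 5, 8),
                      df = c(4, 10, 60))
  own <- mapply(studentized_range_cdf, grid$q, grid$k, grid$df)
  ref <- mapply(ptukey, grid$q, grid$k, grid$df)
  expect_equal(own, ref, tolerance = 1e-6)
})

test_that("Games-Howell reduces to the Welch t-test at k = 2", {
  set.seed(13)
  a <- rnorm(10, 0, 1)
  b <- rnorm(15, 0.8, 2.5)
  gh <- games_howell(list(a = a, b = b))
  tt <- t.test(a, b)
  expect_equal(gh$p.value, tt$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(gh$diff, unname(tt$estimate[1] - tt$estimate[2]))
})

test_that("Games-Howell p-values respect symmetry and invariances", {
  set.seed(14)
  groups <- list(a = rnorm(8), b = rnorm(10, 1, 2), c = rnorm(12, 2, 0.5))
  gh <- games_howell(groups)
  expect_true(all(gh$p.value >= 0 & gh$p.value <= 1))

  # identical groups compare with p = 1
  same <- games_howell(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$p.value, 1)
  expect_equal(same$q, 0)

  # relabelling leaves the p-values untouched
  gh_perm <- games_howell(groups[c(3, 1, 2)])
  key <- function(d) {
    pair <- apply(cbind(d$group1, d$group2), 1,
                  function(r) paste(sort(r), collapse = "-"))
    d$p.value[order(pair)]
  }
  expect_equal(key(gh_perm), key(gh), tolerance = 1e-12)

  # adding a constant changes nothing
  gh_shift <- games_howell(lapply(groups, `+`, 100))
  expect_equal(gh_shift$p.value, gh$p.value, tolerance = 1e-12)
})

test_that("Games-Howell power grows monotone with the mean shift", {
  set.seed(15)
  base <- list(a = rnorm(10, 0, 1), b = rnorm(10, 0, 2))
  ps <- vapply(c(0, 2, 5, 10), function(delta) {
    g <- base
    g$b <- g$b + delta
    games_howell(g)$p.value
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
  expect_lt(ps[4], 1e-6)
})

test_that("replicate correlation matches the covariance formula", {
  tab <- data.frame(replicate = rep(1:2, each = 4),
                    position = rep(sprintf("P%d", 1:4), 2),
                    frac_spindle = c(0.1, 0.2, 0.3, 0.4,
                                     0.12, 0.18, 0.33, 0.41))
  pc <- pearson_between_replicates(tab)
  a <- tab$frac_spindle[1:4]; b <- tab$frac_spindle[5:8]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pc$r, r_hand, tolerance = 1e-12)

  # identical replicates -> 1; negated around the mean -> -1
  tab$frac_spindle[5:8] <- a
  expect_equal(pearson_between_replicates(tab)$r, 1)
  tab$frac_spindle[5:8] <- 2 * mean(a) - a
  expect_equal(pearson_between_replicates(tab)$r, -1)

  # three replicates: mean of the three pairwise correlations
  set.seed(16)
  t3 <- data.frame(replicate = rep(1:3, each = 5),
                   position = rep(sprintf("P%d", 1:5), 3),
                   frac_spindle = runif(15))
  pc3 <- pearson_between_replicates(t3)
  expect_equal(nrow(pc3$pairwise), 3)
  expect_equal(pc3$r, mean(pc3$pairwise$r))

  expect_error(pearson_between_replicates(tab[c(1, 2, 5, 6), ]),
               "at least 3")
})

test_that("variance tests match hand formulas and guard degeneracy", {
  groups <- list(a = c(5.1, 4.9, 5.3, 5.0, 5.2),
                 b = c(3.2, 3.9, 3.3, 3.8, 3.1),
                 c = c(7.5, 7.1, 7.9, 7.2, 7.7))
  bt <- bartlett_groups(groups)
  # hand evaluation of the Bartlett statistic
  n <- vapply(groups, length, 0L)
  v <- vapply(groups, var, 0)
  N <- sum(n); k <- 3
  sp2 <- sum((n - 1) * v) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(v))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(bt$statistic, stat, tolerance = 1e-10)
  expect_equal(bt$df, 2)
  expect_equal(bt$p.value, pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical samples -> statistic 0, p = 1
  same <- bartlett_groups(list(groups$a, groups$a, groups$a))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  ft <- variance_f_test(groups$a, groups$a)
  expect_equal(ft$statistic, 1)
  expect_equal(ft$p.value, 1)
  expect_error(variance_f_test(c(1, 1, 1), groups$a), "zero-variance")
  expect_error(bartlett_groups(list(c(1, 1), c(1, 2))), "zero-variance")
})

test_that("intra-plate variance averages within-replicate variances", {
  tab <- data.frame(replicate = rep(1:3, each = 4),
                    position = rep(sprintf("P%d", 1:4), 3),
                    condition = "NC",
                    frac_spindle = c(1, 2, 3, 4, 2, 4, 6, 8, 0, 0, 0, 0))
  iv <- intra_plate_variance(tab)
  expect_equal(iv$intra_plate_var,
               mean(c(var(c(1, 2, 3, 4)), var(c(2, 4, 6, 8)), 0)))

  # doubling every readout quadruples the variance
  tab2 <- tab
  tab2$frac_spindle <- 2 * tab2$frac_spindle
  expect_equal(intra_plate_variance(tab2)$intra_plate_var,
               4 * iv$intra_plate_var)

  short <- tab[tab$replicate != 1 | tab$position == "P1", ]
  expect_warning(intra_plate_variance(short), "fewer than 2")
})

test_that("the replicate-equivalence formula is exact", {
  expect_equal(replicates_needed(4, 4, 3)$n_a_exact, 3)
  expect_equal(replicates_needed(0, 2, 5)$n_a_exact, 0)
  r <- replicates_needed(7.4^2, 5.3^2, 3)
  expect_equal(r$n_a_exact, 7.4^2 / 5.3^2 * 3, tolerance = 1e-12)
  expect_equal(r$n_a_ceiling, 6)
  expect_error(replicates_needed(1, 0, 3), "var_w")
  expect_error(replicates_needed(-1, 2, 3), "var_a")
})
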