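# Statistics layer: ANOVA vs sums-of-squares oracle, Sidak, Pearson,
# Fisher z, t test.

test_that("degenerate all-equal data give F = 0, p = 1", {
  d <- expand.grid(subj = factor(1:6), day = factor(1:3))
  d$geno <- factor(rep(c("a", "b"), each = 3)[as.integer(d$subj)])
  d$y <- 5
  res <- suppressWarnings(two_way_anova(d, "y", "geno", within = "day",
                                        subject = "subj"))
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
})

test_that("between-subjects two-way ANOVA matches the SS decomposition oracle", {
  set.seed(23)
  d <- expand.grid(A = factor(c("a1", "a2")), B = factor(c("b1", "b2")),
                   rep = 1:5)
  d$y <- rnorm(nrow(d), mean = 2 * (d$A == "a1") + (d$B == "b2") +
                 0.5 * (d$A == "a1" & d$B == "b2"))
  res <- two_way_anova(d, "y", "A", between2 = "B")

  # brute-force balanced 2x2 sums of squares from cell means
  n <- 5
  cell <- tapply(d$y, list(d$A, d$B), mean)
  rowm <- rowMeans(cell); colm <- colMeans(cell); gm <- mean(d$y)
  ss_a <- 2 * n * sum((rowm - gm)^2)
  ss_b <- 2 * n * sum((colm - gm)^2)
  ss_ab <- n * sum((sweep(sweep(cell, 1, rowm), 2, colm) + gm)^2)
  ss_e <- sum((d$y - cell[cbind(as.integer(d$A), as.integer(d$B))])^2)
  df_e <- nrow(d) - 4
  expect_equal(res$statistic[res$effect == "A"], (ss_a / 1) / (ss_e / df_e),
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "B"], (ss_b / 1) / (ss_e / df_e),
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "A:B"], (ss_ab / 1) / (ss_e / df_e),
               tolerance = 1e-8)
  # SS conservation on complete data
  ss_tot <- sum((d$y - gm)^2)
  expect_equal(ss_a + ss_b + ss_ab + ss_e, ss_tot, tolerance = 1e-8)
})

test_that("repeated-measures partition tests the between effect on subjects", {
  set.seed(24)
  d <- expand.grid(subj = factor(1:10), day = factor(1:4))
  d$geno <- factor(rep(c("a", "b"), each = 5)[as.integer(d$subj)])
  d$y <- rnorm(nrow(d)) + 2 * (d$geno == "a")
  res <- two_way_anova(d, "y", "geno", within = "day", subject = "subj")
  expect_equal(res$df2[res$effect == "geno"], 8)        # subjects - groups
  expect_equal(res$df2[res$effect == "day"], 24)        # within residual
  # oracle: classical split-plot F for the between factor from aggregated
  # subject means
  sm <- aggregate(y ~ subj + geno, d, mean)
  fa <- anova(lm(y ~ geno, sm))
  expect_equal(res$statistic[res$effect == "geno"], fa$`F value`[1],
               tolerance = 1e-8)

  # missing values: warning + mixed-effects approximation label
  d$y[1] <- NA
  expect_warning(res2 <- two_way_anova(d, "y", "geno", within = "day",
                                       subject = "subj"), "missing")
  expect_true(all(res2$method == "mixed-effects approximation"))
  expect_error(two_way_anova(d[d$geno == "a", ], "y", "geno",
                             within = "day", subject = "subj"), "levels")
})

test_that("Sidak adjustment: closed form, identity, clipping, monotonicity", {
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5, tolerance = 1e-12)
  expect_equal(sidak_adjust(0.01, 5), 0.0490099501, tolerance = 1e-9)
  expect_equal(sidak_adjust(0.5, 50), 1)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))          # monotone in p
  expect_true(all(sidak_adjust(0.2, 1:10) >= 0.2))         # >= raw
  expect_true(all(diff(sidak_adjust(0.2, 1:10)) >= 0))     # monotone in m
  expect_error(sidak_adjust(1.2, 2), "\\[0, 1\\]")
})

test_that("Pearson r: exact limits and the t-based p-value", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -3 * x + 7)$r, -1)
  set.seed(25)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  pr <- pearson_r(a, b)
  r <- pr$r; n <- pr$n
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(pr$p, 2 * pt(-abs(t), n - 2), tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), "3 complete")
})

test_that("Fisher z contrast: closed form, null, antisymmetry", {
  z0 <- fisher_z_compare(0.4, 30, 0.4, 40)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  fz <- fisher_z_compare(0.8, 53, 0.3, 53)
  expect_equal(fz$z, (atanh(0.8) - atanh(0.3)) / sqrt(2 / 50),
               tolerance = 1e-12)
  expect_equal(fz$z, 3.945463422, tolerance = 1e-7)
  expect_equal(fz$p, 7.964578e-05, tolerance = 1e-6)

  sw <- fisher_z_compare(0.3, 53, 0.8, 53)
  expect_equal(sw$z, -fz$z)
  expect_equal(sw$p, fz$p)
  expect_error(fisher_z_compare(1, 30, 0.2, 30), "< 1")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 30), "exceed 3")
})

test_that("pooled t test matches the hand sums-of-squares computation", {
  g1 <- c(4.1, 5.0, 6.2, 5.5, 4.8)
  g2 <- c(6.0, 7.1, 6.8, 7.5)
  res <- t_test(g1, g2)
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df1, n1 + n2 - 2)
  expect_equal(res$p, 2 * pt(-abs(t_hand), n1 + n2 - 2), tolerance = 1e-10)

  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("significance stars follow the figure convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("habituation genotype-by-time interaction is detectable at study size", {
  hits <- sapply(1:40, function(s) {
    coh <- gen_cohort(c(mutant = 12, wildtype = 15), seed = s)
    d <- do.call(rbind, lapply(seq_len(nrow(coh)), function(i) {
      prof <- gen_habituation_profile(coh[i, ], n_bins = 12, seed = s)
      b <- structure(list(per_bin_cm = as.numeric(prof),
                          total_cm = sum(prof), bin_s = 300),
                     class = "binned_distance")
      data.frame(animal_id = coh$animal_id[i],
                 genotype = as.character(coh$genotype[i]), bin = 1:12,
                 pc = habituation_percent_change(b))
    }))
    a <- two_way_anova(d, "pc", "genotype", within = "bin",
                       subject = "animal_id")
    a$p[a$effect == "genotype:bin"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
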