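# Normality cascade, homogeneity, omnibus tests, effect sizes and the
# decision-tree engine.

grp4 <- rep(paste0("G", 1:4), each = 20)

test_that("per-group Shapiro-Wilk assessment passes, fails and flags", {
  nn <- withr::with_seed(1, rnorm(80, 10, 2))
  expect_true(assess_normality(nn, grp4)$pass)

  ex <- nn
  ex[1:20] <- withr::with_seed(101, exp(rnorm(20)))
  a <- assess_normality(ex, grp4)
  expect_false(a$pass)
  expect_false(a$per_group$pass[a$per_group$group == "G1"])

  const <- nn
  const[1:20] <- 3
  a2 <- assess_normality(const, grp4)
  expect_false(a2$pass)
  expect_true(a2$per_group$degenerate[a2$per_group$group == "G1"])

  # groups too small to test do not block the pass
  small <- assess_normality(c(1.1, 2.3, rnorm(20)),
                            c("tiny", "tiny", rep("big", 20)))
  expect_false(small$per_group$testable[small$per_group$group == "tiny"])
})

test_that("transform cascade picks the first normalising transform", {
  nn <- withr::with_seed(1, rnorm(80, 10, 2))
  expect_equal(transform_cascade(nn, grp4)$transform, "none")

  sq <- withr::with_seed(1, rnorm(80, 2, 0.6)^2)
  cs <- transform_cascade(sq, grp4)
  expect_equal(cs$transform, "sqrt")
  expect_true(cs$normal)
  expect_equal(cs$values, sqrt(sq))

  ln <- withr::with_seed(1, rlnorm(80, 1, 1.6))
  cl <- transform_cascade(ln, grp4)
  expect_equal(cl$transform, "ln")
  expect_true(cl$normal)

  bim <- make_bimodal_groups()
  cb <- transform_cascade(bim$values, bim$group)
  expect_false(cb$normal)

  # negative values: sqrt branch skipped, ln impossible -> untransformable
  neg <- withr::with_seed(101, exp(rnorm(60)))
  neg <- c(neg - 2)
  cn <- transform_cascade(neg, rep(c("a", "b", "c"), each = 20))
  if (!cn$normal) expect_true(isTRUE(cn$untransformable))
})

test_that("Levene's test calibrates and degenerates sanely", {
  eq <- make_grouped(20, means = c(5, 5, 5, 5), sds = 1, seed = 8)
  expect_gt(homogeneity(eq$values, eq$group)$p, 0.05)

  het <- make_grouped(20, means = c(5, 5, 5, 5), sds = c(1, 1, 1, 5),
                      seed = 8)
  expect_lt(homogeneity(het$values, het$group)$p, 0.05)

  dg <- homogeneity(c(2, 2, 2, 2), c("a", "a", "b", "b"))
  expect_equal(dg$p, 1)
  expect_true(dg$degenerate)
})

test_that("one-way ANOVA matches hand sums-of-squares and the t^2 identity", {
  v <- c(1, 2, 3, 2, 3, 4)
  g <- rep(c("a", "b"), each = 3)
  res <- one_way_anova(v, g)
  # explicit SS arithmetic oracle
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)

  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero within-group variance")
})

test_that("null-simulation F averages near 1", {
  withr::local_seed(123)
  fs <- replicate(500, {
    one_way_anova(rnorm(24), rep(c("a", "b", "c"), each = 8))$statistic
  })
  expect_lt(abs(mean(fs) - 1), 0.2)
})

test_that("Welch ANOVA matches its direct formula and the Welch t^2 identity", {
  het <- make_grouped(c(10, 15, 20, 12), means = c(5, 5.5, 6, 5),
                      sds = c(1, 2, 3, 1.5), seed = 13)
  res <- welch_anova(het$values, het$group)
  # brute-force evaluation of the Welch formula
  ni <- tapply(het$values, het$group, length)
  mi <- tapply(het$values, het$group, mean)
  vi <- tapply(het$values, het$group, var)
  wi <- ni / vi
  k <- length(ni)
  mw <- sum(wi * mi) / sum(wi)
  num <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  f_hand <- num / (1 + 2 * lam * (k - 2))
  df2_hand <- 1 / (3 * lam)
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)
  expect_equal(res$df2, df2_hand, tolerance = 1e-10)

  # balanced groups rescaled to identical sample SDs: Welch F approaches
  # the classical F (they differ only through the Welch denominator)
  eq <- make_grouped(20, means = c(5, 5, 6, 5.5), sds = 1, seed = 21)
  eq$values <- unlist(lapply(split(eq$values, eq$group), function(v) {
    mean(v) + (v - mean(v)) / sd(v)
  }), use.names = FALSE)
  eq$group <- sort(eq$group)
  expect_equal(welch_anova(eq$values, eq$group)$statistic,
               one_way_anova(eq$values, eq$group)$statistic,
               tolerance = 0.05)

  two <- make_grouped(12, means = c(4, 6), sds = c(1, 3), seed = 5)
  wr <- welch_anova(two$values, two$group)
  wt <- t.test(two$values ~ two$group)
  expect_equal(wr$statistic, unname(wt$statistic)^2, tolerance = 1e-10)
  expect_equal(wr$df2, unname(wt$parameter), tolerance = 1e-10)

  expect_error(welch_anova(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "zero variance")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))$statistic,
               0)
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))$p, 1)

  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  n <- 6
  rs <- tapply(rank(v), g, sum)
  h_hand <- 12 / (n * (n + 1)) * sum(rs^2 / 2) - 3 * (n + 1)
  expect_equal(kruskal_wallis(v, g)$statistic, h_hand, tolerance = 1e-12)
  expect_equal(kruskal_wallis(v, g)$df, 2)
})

test_that("H computation is stable under label permutation (tie-corrected formula oracle)", {
  withr::local_seed(17)
  v <- round(rlnorm(30, 1, 0.5), 1)  # induces ties
  g0 <- rep(c("a", "b", "c"), each = 10)
  h_formula <- function(v, g) {
    n <- length(v)
    rk <- rank(v)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(rk, g, function(r) length(r) * mean(r)^2)) - 3 * (n + 1)
    ties <- table(v)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  for (i in 1:200) {
    g <- sample(g0)
    expect_equal(kruskal_wallis(v, g)$statistic, h_formula(v, g),
                 tolerance = 1e-10)
  }
})

test_that("omega-squared reproduces printed effect sizes and the SS definition", {
  expect_equal(omega_squared(1, 3, 40), 0)
  expect_equal(round(omega_squared(13.5, 3, 75), 3), 0.322)
  expect_equal(round(omega_squared(0.114, 3, 76), 3), -0.034)

  withr::local_seed(31)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(4:8, 1)
    v <- rnorm(k * n)
    g <- rep(seq_len(k), each = n)
    grand <- mean(v)
    ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
    ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
    sst <- ssb + ssw
    df1 <- k - 1; df2 <- k * n - k
    msw <- ssw / df2
    f <- (ssb / df1) / msw
    expect_equal(omega_squared(f, df1, df2),
                 (ssb - df1 * msw) / (sst + msw), tolerance = 1e-12)
  }
})

test_that("epsilon-squared follows H/(n-1) and is rank-invariant", {
  expect_equal(epsilon_squared(0, 10), 0)
  expect_equal(round(epsilon_squared(14.6, 76), 3), 0.195)
  expect_error(epsilon_squared(1, 1), "n_total")

  withr::local_seed(19)
  for (i in 1:10) {
    v <- rlnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    kw1 <- kruskal_wallis(v, g)
    kw2 <- kruskal_wallis(exp(v / 2), g)  # strictly monotone transform
    expect_equal(epsilon_squared(kw1$statistic, kw1$n_total),
                 epsilon_squared(kw2$statistic, kw2$n_total),
                 tolerance = 1e-12)
  }
})

test_that("decision tree routes constructed fixtures to the right branch", {
  tb <- tibble::tibble(
    animal_id = sprintf("f%02d", 1:80),
    group = grp4,
    homo = withr::with_seed(1, rnorm(80, 10, 2)),
    hetero = withr::with_seed(8, c(rnorm(20, 10, 1), rnorm(20, 10, 1),
                                   rnorm(20, 10, 1), rnorm(20, 10, 4))),
    skewed = make_bimodal_groups(seed = 7)$values
  )
  tb <- as_biomarker_table(tb)

  r1 <- compare_groups(tb, "homo")
  expect_equal(r1$trail$branch, "anova_tukey")
  expect_equal(r1$statistic_kind, "F")
  expect_equal(r1$effect_size_kind, "omega2")

  r2 <- compare_groups(tb, "hetero")
  expect_equal(r2$trail$branch, "welch_gameshowell")
  expect_equal(r2$statistic_kind, "F_welch")
  expect_true(r2$effect_size_approx)

  r3 <- compare_groups(tb, "skewed")
  expect_equal(r3$trail$branch, "kruskal_dunn")
  expect_equal(r3$statistic_kind, "H")
  expect_equal(r3$effect_size_kind, "epsilon2")
  expect_equal(r3$effect_size,
               epsilon_squared(r3$statistic, r3$n_total))
})

test_that("the decision trail is deterministic and post-hoc tables well-formed", {
  tb <- make_table(n_per_group = 10, n_biomarkers = 2, seed = 77,
                   groups = c("A1", "A2", "A3", "A4"))
  a <- compare_groups(tb, "bm1")
  b <- compare_groups(tb, "bm1")
  expect_identical(a$trail, b$trail)
  expect_identical(a$p, b$p)

  for (r in list(a, compare_groups(tb, "bm2"))) {
    expect_equal(nrow(r$posthoc), choose(4, 2))
    expect_true(all(r$posthoc$p_adj >= 0 & r$posthoc$p_adj <= 1))
  }
  expect_true(a$p >= 0 && a$p <= 1)
})

test_that("insufficient data yields a skip record, not an abort", {
  tb <- tibble::tibble(animal_id = c("f1", "f2", "f3"),
                       group = c("A1", "A1", "A2"),
                       bm = c(1.2, 1.5, NA))
  tb <- as_biomarker_table(tb)
  r <- compare_groups(tb, "bm")
  expect_true(r$skipped)
  all_res <- compare_all_biomarkers(tb)
  expect_true(all_res$summary$skipped[1])
})
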