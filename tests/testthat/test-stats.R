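test_that("pre-treatment averaging follows the stated missing-session rules", {
  tab <- data.frame(
    subject = c("MS01", "MS01", "MS02", "MS03", "MS03", "HC01"),
    group = c("MS", "MS", "MS", "MS", "MS", "HC"),
    session = c(1, 2, 1, 1, 2, 1),
    cvr_gm = c(0.08, 0.10, 0.095, NA, NA, 0.11),
    cvr_wm = c(0.05, 0.07, 0.06, NA, NA, 0.07))
  pre <- pretreatment_average(tab)
  expect_equal(pre$pre_cvr_gm[pre$subject == "MS01"], 0.09)
  expect_equal(pre$pre_cvr_gm[pre$subject == "MS02"], 0.095)  # fallback
  expect_false("MS03" %in% pre$subject)
  expect_identical(attr(pre, "excluded"), "MS03")
  expect_error(pretreatment_average(tab[tab$group == "HC", ]), "no MS")
})

test_that("t-tests match hand-computed pooled and paired formulas", {
  r <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  # pooled SD 1, SE sqrt(2/3) = 0.8165 -> t = -3.674, dof 4
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$dof, 4)

  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    o <- pooled_t_oracle(a, b); got <- ttest_unpaired(a, b)
    expect_equal(got$statistic, o$t, tolerance = 1e-9)
    expect_equal(got$p_value, o$p, tolerance = 1e-9)
    x <- rnorm(6); y <- rnorm(6, 0.3)
    op <- paired_t_oracle(x, y); gp <- ttest_paired(x, y)
    expect_equal(gp$statistic, op$t, tolerance = 1e-9)
    expect_equal(gp$p_value, op$p, tolerance = 1e-9)
  }

  same <- c(0.3, 1.2, -0.5, 0.8)
  r0 <- ttest_unpaired(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(ttest_paired(same + 1, same), "degenerate")
  expect_error(ttest_unpaired(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("repeated-measures ANOVA matches SS-partition and aov oracles", {
  wide <- matrix(c(0.08, 0.09, 0.11,
                   0.07, 0.08, 0.09,
                   0.10, 0.09, 0.13,
                   0.09, 0.11, 0.12), 4, 3, byrow = TRUE)
  got <- ranova_oneway(wide)
  o <- ranova_oracle(wide)
  expect_equal(got$statistic, o$f, tolerance = 1e-9)
  expect_equal(got$dof, c(o$df1, o$df2))
  expect_equal(got$p_value, o$p, tolerance = 1e-9)

  # cross-check against the stratified aov fit
  df <- data.frame(y = as.vector(wide),
                   subj = factor(rep(1:4, 3)),
                   sess = factor(rep(1:3, each = 4)))
  aa <- summary(aov(y ~ sess + Error(subj), data = df))
  f_aov <- aa[["Error: Within"]][[1]]["sess", "F value"]
  expect_equal(got$statistic, f_aov, tolerance = 1e-9)

  # constant-within-subject data: no condition effect
  flat <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  g0 <- ranova_oneway(flat)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)

  # incomplete subjects dropped and counted
  wide_na <- rbind(wide, c(0.1, NA, 0.1))
  gna <- ranova_oneway(wide_na)
  expect_equal(gna$statistic, got$statistic, tolerance = 1e-12)
  expect_match(gna$note, "1 incomplete")
  expect_error(ranova_oneway(wide[1:2, ]), "3 complete")
})

test_that("repeated-measures ANOVA detects a session-3 shift", {
  # subject effect SD 0.02, residual SD 0.01, session means
  # (0.091, 0.091, 0.107): rejection rate at alpha = 0.05 above 80%
  set.seed(12)
  mu <- c(0.091, 0.091, 0.107)
  rej <- 0; n_sim <- 200
  for (i in seq_len(n_sim)) {
    wide <- matrix(mu, 20, 3, byrow = TRUE) + rnorm(20, 0, 0.02) +
      matrix(rnorm(60, 0, 0.01), 20, 3)
    if (ranova_oneway(wide)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_sim, 0.8)
})

test_that("Pearson correlation and Fisher z match closed forms", {
  expect_equal(pearson_cor(1:3, 1:3)$estimate, 1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$estimate, 0.6,
               tolerance = 1e-9)
  set.seed(4)
  x <- rnorm(6); y <- rnorm(6)
  o <- pearson_oracle(x, y); g <- pearson_cor(x, y)
  expect_equal(g$estimate, o$r, tolerance = 1e-9)
  expect_equal(g$statistic, o$t, tolerance = 1e-9)
  expect_equal(g$p_value, o$p, tolerance = 1e-9)
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.6), atanh(0.6))
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("normality screen separates normal from two-point samples", {
  set.seed(5)
  d <- ks_normality(rnorm(200), n_mc = 500, seed = 2)
  expect_gte(d$statistic, 0); expect_lte(d$statistic, 1)
  expect_gt(d$p_value, 0.05)
  two_pt <- rep(c(-1, 1), 100)
  expect_lt(ks_normality(two_pt, n_mc = 500, seed = 2)$p_value, 0.01)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  # D statistic agrees with the established Lilliefors implementation
  skip_if_not_installed("nortest")
  x <- rnorm(50)
  expect_equal(ks_normality(x, n_mc = 100)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-9)
})

test_that("cohort battery reproduces the generating structure and is row-order invariant", {
  co <- make_cohort(cohort_spec(seed = 21))
  tab <- co$truth
  # use the generated truths as the per-subject summaries (estimation-free)
  names(tab)[names(tab) == "cvr_gm_true"] <- "cvr_gm"
  names(tab)[names(tab) == "cvr_wm_true"] <- "cvr_wm"
  names(tab)[names(tab) == "lesion_cvr_true"] <- "cvr_lesion"
  res <- analyze_cohort(tab)
  expect_s3_class(res$tests$hc_vs_ms_gm, "stat_result")
  # restoration effect: Monte-Carlo over cohort seeds — the change is
  # negatively correlated with pre-treatment level, usually significantly
  mc <- sapply(1:10, function(s) {
    tb <- make_cohort(cohort_spec(seed = 100 + s))$truth
    names(tb)[match(c("cvr_gm_true", "cvr_wm_true", "lesion_cvr_true"),
                    names(tb))] <- c("cvr_gm", "cvr_wm", "cvr_lesion")
    r <- analyze_cohort(tb)$tests$delta_vs_pre_gm
    c(r$estimate, r$p_value)
  })
  expect_gte(sum(mc[1, ] < 0), 9)           # direction
  expect_gte(sum(mc[2, ] < 0.05), 6)        # power at n ~ 21 complete cases
  expect_lt(res$tests$delta_vs_pre_wm$estimate, 0)
  # lesion CVR depressed relative to WM at session 1
  expect_equal(res$tests$lesion_vs_wm_s1$direction, "x < y")
  # HC vs MS direction matches the generating means
  expect_equal(res$tests$hc_vs_ms_gm$direction, "a > b")
  # session-3 lesion test has too few positive subjects and degenerates
  # gracefully (message, not an error)
  expect_true(is.character(res$tests$lesion_vs_wm_s3) ||
                inherits(res$tests$lesion_vs_wm_s3, "stat_result"))

  # row order and subject relabelling do not change the results
  perm <- sample(nrow(tab))
  res2 <- analyze_cohort(tab[perm, ])
  for (nm in c("hc_vs_ms_gm", "ranova_gm", "pre_vs_on_wm", "delta_vs_pre_gm"))
    expect_equal(res2$tests[[nm]]$statistic, res$tests[[nm]]$statistic,
                 tolerance = 1e-12)
})
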