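test_that("rm ANOVA reproduces the design degrees of freedom at n = 14", {
  set.seed(301)
  tab <- null_cell_table(n_subjects = 14)
  res <- rm_anova_2way(tab)
  eff <- res$effects
  expect_equal(eff$df1[eff$effect == "condition"], 2)
  expect_equal(eff$df2[eff$effect == "condition"], 26)
  expect_equal(eff$df1[eff$effect == "familiarity"], 1)
  expect_equal(eff$df2[eff$effect == "familiarity"], 13)
  expect_equal(eff$df1[eff$effect == "interaction"], 2)
  expect_equal(eff$df2[eff$effect == "interaction"], 26)
})

test_that("rm ANOVA decomposition matches brute-force sums of squares and aov", {
  set.seed(311)
  tab <- null_cell_table(n_subjects = 4)
  tab$value_ms <- tab$value_ms + ifelse(tab$condition == "use", 1.5, 0)
  res <- rm_anova_2way(tab)
  eff <- res$effects

  # brute-force marginal-mean SS
  y <- tab$value_ms; gm <- mean(y)
  ss <- function(means, mult) mult * sum((means - gm)^2)
  m_a <- tapply(y, tab$condition, mean)
  m_b <- tapply(y, tab$familiarity, mean)
  expect_equal(eff$ss[eff$effect == "condition"], ss(m_a, 2 * 4))
  expect_equal(eff$ss[eff$effect == "familiarity"], ss(m_b, 3 * 4))

  # decomposition sums to the total SS
  total <- sum((y - gm)^2)
  expect_equal(sum(eff$ss) + sum(eff$error_ss) + res$subject_ss, total,
               tolerance = 1e-12)

  # independent oracle: aov with Error(subject/(condition*familiarity))
  fit <- summary(stats::aov(
    value_ms ~ condition * familiarity +
      Error(factor(subject) / (condition * familiarity)), data = tab))
  get_f <- function(stratum, term) {
    t <- fit[[stratum]][[1]]
    t[trimws(rownames(t)) == term, "F value"]
  }
  expect_equal(eff$f[eff$effect == "condition"],
               get_f("Error: factor(subject):condition", "condition"))
  expect_equal(eff$f[eff$effect == "familiarity"],
               get_f("Error: factor(subject):familiarity", "familiarity"))
  expect_equal(eff$f[eff$effect == "interaction"],
               get_f("Error: factor(subject):condition:familiarity",
                     "condition:familiarity"))
})

test_that("rm ANOVA F is invariant under affine rescaling and zero for flat effects", {
  set.seed(321)
  tab <- null_cell_table(n_subjects = 6)
  res1 <- rm_anova_2way(tab)
  tab2 <- tab
  tab2$value_ms <- 3.7 * tab$value_ms - 12
  res2 <- rm_anova_2way(tab2)
  expect_equal(res2$effects$f, res1$effects$f, tolerance = 1e-10)

  # identical values across conditions within each subject x familiarity:
  # condition SS (and interaction SS) are exactly zero
  flat <- tab
  flat$value_ms <- ave(tab$value_ms, tab$subject, tab$familiarity)
  res3 <- rm_anova_2way(flat)
  expect_equal(res3$effects$ss[res3$effects$effect == "condition"], 0)
  expect_error(rm_anova_2way(tab[-1, ]), "complete and balanced")
})

test_that("degenerate zero-variance tables are flagged, not masked", {
  tab <- expand.grid(subject = sprintf("S%d", 1:4),
                     condition = c("free_viewing", "lift", "use"),
                     familiarity = c("familiar", "unfamiliar"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$value_ms <- 5
  res <- rm_anova_2way(tab)
  expect_true(res$degenerate)
  expect_true(all(is.na(res$effects$f)))
})

test_that("Shaffer constants match exhaustive partition enumeration for k <= 6", {
  expect_equal(shaffer_constants(2), 1L)
  expect_equal(shaffer_constants(3), c(3L, 1L, 1L))
  for (k in 3:6) {
    expect_equal(as.numeric(shaffer_constants(k)), brute_shaffer(k),
                 info = paste("k =", k))
  }
})

test_that("the Shaffer procedure rejects sequentially and stops at the first failure", {
  dec <- shaffer_pairwise(c(0.001, 0.02, 0.04), k_means = 3)
  expect_true(all(dec$reject)) # critical values 0.05/3, 0.05, 0.05
  expect_equal(sort(dec$critical_alpha), sort(0.05 / c(3, 1, 1)))

  none <- shaffer_pairwise(rep(1, 3), k_means = 3)
  expect_false(any(none$reject))

  # stopping: the first failure retains everything after it, even hypotheses
  # that would pass their own critical value (k = 4: criticals
  # alpha/6, alpha/3, alpha/3, alpha/3, alpha/2, alpha)
  stopped <- shaffer_pairwise(c(0.005, 0.02, 0.021, 0.022, 0.023, 0.03),
                              k_means = 4)
  expect_equal(stopped$reject[order(stopped$p_raw)],
               c(TRUE, rep(FALSE, 5)))
  expect_error(shaffer_pairwise(c(0.1, 0.2), k_means = 3), "expected 3")
})

test_that("Shaffer rejections dominate Bonferroni and are dominated by unadjusted", {
  set.seed(331)
  for (k in c(3, 4)) {
    m <- k * (k - 1) / 2
    for (rep in 1:50) {
      p <- runif(m)^2
      dec <- shaffer_pairwise(p, k_means = k, alpha = 0.05)
      bonf <- p <= 0.05 / m
      unadj <- p <= 0.05
      expect_true(all(dec$reject[bonf]))
      expect_true(all(unadj[dec$reject]))
      # monotone: no rejected hypothesis has larger p than a retained one
      if (any(dec$reject) && any(!dec$reject)) {
        expect_lt(max(p[dec$reject]), min(p[!dec$reject]) + 1e-15)
      }
    }
  }
})

test_that("simple effects find constructed separation and match the closed-form paired t", {
  set.seed(341)
  tab <- null_cell_table(n_subjects = 14, sd_noise = 0.01)
  boost <- tab$condition == "use" & tab$familiarity == "unfamiliar"
  tab$value_ms[boost] <- tab$value_ms[boost] + 100
  se <- simple_effects(tab)
  fwc <- se$familiarity_within_condition
  expect_true(fwc$reject[fwc$family == "familiarity | use"])
  expect_false(fwc$reject[fwc$family == "familiarity | lift"])

  # paired t equals the hand-computed mean / standard-error ratio
  x <- c(3.1, 4.2, 2.8, 5.0); y <- c(2.9, 3.1, 3.0, 3.8)
  tt <- paired_t_test(x, y)
  d <- x - y
  expect_equal(tt$t, mean(d) / (sd(d) / 2))
  expect_equal(tt$df, 3)
  oracle <- t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(oracle$statistic))
  expect_equal(tt$p, oracle$p.value)
})

test_that("null simple-effect families keep the family-wise error at alpha", {
  set.seed(351)
  n_sims <- 400
  fwe <- 0
  for (i in seq_len(n_sims)) {
    tab <- null_cell_table(n_subjects = 14)
    se <- simple_effects(tab)
    cwf <- se$condition_within_familiarity
    fam <- cwf[cwf$family == "conditions | familiar", ]
    if (any(fam$reject)) fwe <- fwe + 1
  }
  rate <- fwe / n_sims
  # binomial 99% MC envelope around 0.05 at 400 sims
  expect_lte(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("Mann-Whitney U matches brute-force counting and exact enumeration", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U_a, 0)
  expect_equal(sep$U_b, 9)

  sym <- mann_whitney_u(c(2, 7, 7, 9), c(2, 7, 7, 9))
  expect_equal(sym$U_a, 8)
  expect_equal(sym$U_b, 8)

  set.seed(361)
  for (rep in 1:20) {
    a <- sample(1:10, sample(3:6, 1), replace = TRUE)
    b <- sample(1:10, sample(3:6, 1), replace = TRUE)
    res <- mann_whitney_u(a, b)
    brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(res$U_a, brute)
    expect_equal(res$U_a + res$U_b, length(a) * length(b))
  }

  # tie-free exact p equals wilcox.test's exact p
  for (rep in 1:10) {
    a <- sample(seq(0.1, 50, by = 0.7), 6)
    b <- sample(seq(0.13, 50, by = 0.71), 6)
    res <- mann_whitney_u(a, b)
    expect_match(res$method, "exact")
    oracle <- wilcox.test(a, b, exact = TRUE)
    expect_equal(res$U_a, unname(oracle$statistic))
    expect_equal(res$p, oracle$p.value)
  }

  # heavy ties take the corrected normal approximation, as wilcox.test does
  a <- c(5, 5, 4, 5, 4, 5)
  b <- c(1, 1, 1, 2, 1, 3)
  res <- mann_whitney_u(a, b)
  expect_match(res$method, "normal")
  oracle <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("the variance gate picks Welch only when the F test rejects", {
  same <- variance_gated_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$f_statistic, 1)
  expect_equal(same$branch, "student")

  set.seed(371)
  a <- rnorm(6, sd = 10); b <- rnorm(6, sd = 1)
  res <- variance_gated_t_test(a, b)
  expect_equal(res$branch, "welch")
  f_or <- var.test(a, b)
  expect_equal(res$f_statistic, unname(f_or$statistic))
  expect_equal(res$f_p, f_or$p.value)
  welch <- t.test(a, b)
  expect_equal(res$t, unname(welch$statistic))
  expect_equal(res$df, unname(welch$parameter)) # Satterthwaite closed form
  expect_equal(res$p, welch$p.value)

  c1 <- rnorm(8); c2 <- rnorm(8) + 0.5
  res2 <- variance_gated_t_test(c1, c2)
  if (res2$branch == "student") {
    student <- t.test(c1, c2, var.equal = TRUE)
    expect_equal(res2$t, unname(student$statistic))
    expect_equal(res2$p, student$p.value)
  }
  deg <- variance_gated_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
})

test_that("per-effect type-I error is calibrated at the nominal level", {
  set.seed(381)
  n_sims <- 600
  rej <- c(condition = 0, familiarity = 0, interaction = 0)
  for (i in seq_len(n_sims)) {
    res <- rm_anova_2way(null_cell_table(n_subjects = 14))
    p <- setNames(res$effects$p, res$effects$effect)
    rej <- rej + (p[names(rej)] <= 0.05)
  }
  rates <- rej / n_sims
  # F tests are exact under iid normal cells: rates near 0.05
  expect_true(all(rates >= 0.025 & rates <= 0.075))
})
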