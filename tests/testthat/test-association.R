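test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(61)
  for (n in c(1, 10, 137, 1000)) {
    p <- runif(n)
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # order preservation: ranking by q never contradicts ranking by p
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("per-variant GLM association has calibrated type-I error", {
  withr::local_seed(62)
  n <- 500; m <- 1000
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, sprintf("v%d", 1:m)))
  y <- rnorm(n, 10, 3)
  res <- gwas_glm(dos, y)$results
  frac <- mean(res$p < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), se3)
  expect_equal(sum(res$q < 0.05), 0L)
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("GLM skips monomorphic, rare and singular designs with reasons", {
  withr::local_seed(63)
  n <- 100
  dos <- cbind(mono = rep(1L, n), rare = c(1L, rep(0L, n - 1)),
               ok = rbinom(n, 2, 0.4))
  y <- rnorm(n)
  out <- gwas_glm(dos, y, maf_min = 0.01)
  expect_setequal(out$skipped$variant, c("mono", "rare"))
  expect_equal(out$results$variant, "ok")
  # dosage collinear with a covariate
  d2 <- cbind(dup = dos[, "ok"])
  out2 <- gwas_glm(d2, y, covariates = data.frame(cv = dos[, "ok"]))
  expect_equal(out2$skipped$reason, "singular_design")
})

test_that("a planted effect is detected with high power at FDR 0.05", {
  withr::local_seed(64)
  hits <- 0L
  for (rep in 1:60) {
    n <- 500
    dos <- matrix(rbinom(n * 21, 2, 0.2), n, 21,
                  dimnames = list(NULL, c("causal", sprintf("null%d", 1:20))))
    y <- 8 + 2 * dos[, "causal"] + rnorm(n, 0, 3)
    res <- gwas_glm(dos, y)$results
    if (res$q[res$variant == "causal"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})

test_that("group comparisons match their textbook formulas", {
  # two identical groups: t = 0, p = 1
  g <- factor(rep(c("a", "b"), each = 4))
  v <- rep(c(1, 2, 3, 4), 2)
  t0 <- group_compare(v, g, "unpaired_t")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # one-sample t of two rare carriers against a reference mean of 5 g/L
  t1 <- group_compare(c(48.50, 118.87), test = "one_sample_t", mu0 = 5)
  expect_equal(t1$statistic, (mean(c(48.50, 118.87)) - 5) /
                 (sd(c(48.50, 118.87)) / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(t1$statistic, 3), 2.236)
  # 3-group ANOVA F equals the manual sum-of-squares decomposition
  vals <- c(1, 2, 3, 4, 6, 8, 7, 9, 11)
  grp <- factor(rep(c("g1", "g2", "g3"), each = 3))
  an <- group_compare(vals, grp, "anova_dunnett")
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2)))
  f_manual <- (ssb / 2) / (ssw / 6)
  expect_equal(an$statistic, f_manual, tolerance = 1e-12)
  expect_equal(nrow(an$comparisons), 2L)   # Dunnett vs reference group
  expect_true(all(an$comparisons$p_adjusted >= 0 &
                    an$comparisons$p_adjusted <= 1))
  expect_error(group_compare(c(1, 2), factor(c("a", "b")), "unpaired_t"),
               ">= 2 values")
})

test_that("Kaplan-Meier and log-rank behave on canonical cases", {
  # identical groups: chi-square 0, p 1
  r <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                  rep(c("a", "b"), each = 3))
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # hand-computed 6-subject table
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 0, 0, 0)
  grp <- c("a", "b", "a", "b", "a", "b")
  r2 <- km_logrank(times, events, grp)
  oe <- survival::survdiff(survival::Surv(times, events) ~ grp)
  expect_equal(r2$chisq, unname(oe$chisq))
  expect_equal(r2$df, 1L)
  # manual expected events for group a: events at t=1 (a), 2 (b), 3 (a);
  # risk sets 6, 5, 4 with a at risk 3, 2, 2
  expect_equal(sum(oe$exp[1]), 3 / 6 + 2 / 5 + 2 / 4)
  # KM closed form without censoring: S(t1) = 1 - d/n
  fit <- survival::survfit(survival::Surv(c(1, 2, 3, 4), c(1, 1, 1, 1)) ~ 1)
  expect_equal(fit$surv[1], 1 - 1 / 4)
  # degenerate inputs
  expect_error(km_logrank(1:4, c(1, 1, 0, 0), rep("a", 4)), ">=2 groups")
  expect_error(km_logrank(1:4, rep(0, 4), rep(c("a", "b"), 2)),
               "at least one event")
})

test_that("burden scores count beneficial alleles and recover the trend", {
  dos <- rbind(S1 = c(rs_a = 0L, rs_b = 0L, rs_c = 1L),
               S2 = c(rs_a = 1L, rs_b = 1L, rs_c = 0L),
               S3 = c(rs_a = 2L, rs_b = 0L, rs_c = 0L))
  b <- burden_score(dos, c("rs_a", "rs_b"))
  expect_equal(b$score, c(0L, 2L, 2L))
  expect_warning(burden_score(dos, c("rs_a", "rs_missing")), "rs_missing")
  withr::local_seed(65)
  n <- 400
  d <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
              dimnames = list(NULL, c("b1", "b2", "b3")))
  y <- 6 + 1.5 * rowSums(d) + rnorm(n, 0, 3)
  tr <- burden_score(d, c("b1", "b2", "b3"), phenotype = y)$trend
  expect_lt(abs(tr$slope - 1.5), 3 * tr$se)
  expect_lt(tr$p, 0.01)
})
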