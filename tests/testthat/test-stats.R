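# Group comparisons, regressions, residualization, summaries.

test_that("percent_difference is the exact mean ratio", {
  v <- c(rep(100, 4), rep(128, 4), rep(144, 4))
  cl <- rep(c("none", "mendelian", "gwas"), each = 4)
  pd <- percent_difference(v, cl)
  expect_equal(unname(pd["mendelian"]), 28)
  expect_equal(unname(pd["gwas"]), 44)
  expect_equal(unname(percent_difference(rep(5, 6),
                                         rep(c("none", "gwas"), 3))["gwas"]), 0)
  expect_error(percent_difference(1:3, rep("gwas", 3)), "baseline")
  expect_error(percent_difference(c(0, 0, 1), c("none", "none", "gwas")),
               "zero")
  # missing rows are dropped
  pd2 <- percent_difference(c(100, NA, 150), c("none", "none", "gwas"))
  expect_equal(unname(pd2["gwas"]), 50)
})

test_that("one_way_anova matches its degenerate and algebraic cases", {
  a <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # two groups: F equals the squared pooled t
  set.seed(21)
  x <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  tt <- welch_t_test(x[g == "a"], x[g == "b"], pooled = TRUE)
  ff <- one_way_anova(x, g)
  expect_equal(ff$F, tt$t^2, tolerance = 1e-10)
  expect_equal(ff$p, tt$p, tolerance = 1e-10)
  expect_error(one_way_anova(1:5, rep("a", 5)), "two groups")
  # all-degenerate variance -> missing p with F reported
  d <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.na(d$p))
})

test_that("welch_t_test handles identity, separation and matches t.test", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  sep <- welch_t_test(c(0, 0, 1e-9), c(1, 1, 1 + 1e-9))
  expect_lt(sep$p, 1e-6)
  deg <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(deg$p, 1)
  set.seed(22)
  x <- rnorm(9); y <- rnorm(14, 0.8)
  ours <- welch_t_test(x, y)
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  pooled <- welch_t_test(x, y, pooled = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$p, refp$p.value, tolerance = 1e-12)
})

test_that("standardized regression equals Pearson r with one predictor", {
  set.seed(23)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  fit <- standardized_regression(y, data.frame(x = x))
  expect_equal(fit$coefficients$beta, cor(x, y), tolerance = 1e-10)
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-10)
})

test_that("orthogonal predictors give marginal correlations as coefficients", {
  set.seed(24)
  n <- 64
  X0 <- scale(matrix(rnorm(n * 3), ncol = 3), scale = FALSE)
  Q <- qr.Q(qr(X0))                       # centred and exactly orthogonal
  Q <- sweep(Q, 2, apply(Q, 2, sd), "/")  # unit variance, still orthogonal
  y <- Q %*% c(0.5, -0.3, 0.2) + rnorm(n, sd = 0.3)
  fit <- standardized_regression(as.numeric(y), as.data.frame(Q))
  marg <- apply(Q, 2, cor, y = y)
  expect_equal(fit$coefficients$beta, unname(marg), tolerance = 1e-8)
})

test_that("standardized coefficients are scale-invariant and complete-case", {
  set.seed(25)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- X$a - X$b + rnorm(50)
  f1 <- standardized_regression(y, X)
  X2 <- X; X2$a <- X2$a * 1000
  f2 <- standardized_regression(y, X2)
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-10)
  # row order does not matter for complete-case handling
  X3 <- X; X3$a[c(3, 7)] <- NA
  p <- sample(50)
  f3 <- standardized_regression(y, X3)
  f4 <- standardized_regression(y[p], X3[p, ])
  expect_equal(f3$coefficients$beta, f4$coefficients$beta, tolerance = 1e-10)
  expect_equal(f3$n, 48)
  # collinearity and constants are errors
  expect_error(standardized_regression(y, data.frame(a = X$a, b = X$a)),
               "collinear")
  expect_error(standardized_regression(y, data.frame(a = X$a, b = 1)),
               "constant")
})

test_that("residualize returns mean-zero residuals aligned to rows", {
  set.seed(26)
  X <- data.frame(x = rnorm(40))
  y <- 2 + 3 * X$x + rnorm(40)
  r <- residualize(y, X)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  # exact linear response -> residuals ~ 0
  r0 <- residualize(2 + 3 * X$x, X)
  expect_equal(max(abs(r0)), 0, tolerance = 1e-9)
  # response orthogonal to the design (intercept and slope) passes through
  # unchanged apart from centring
  z <- rnorm(40)
  M <- cbind(1, X$x)
  z <- as.numeric(z - M %*% solve(crossprod(M), crossprod(M, z)))
  rz <- residualize(z, X)
  expect_equal(rz, z - mean(z), tolerance = 1e-9)
  # alignment with missing rows
  y2 <- y; y2[5] <- NA
  r2 <- residualize(y2, X)
  expect_true(is.na(r2[5]))
  expect_equal(length(r2), 40)
  # log-log variant requires positive values
  expect_error(residualize(c(-1, y[-1]), X, log_log = TRUE), "positive")
})

test_that("summary_stats computes CV and normal CIs", {
  s <- summary_stats(c(1, 1, 1))
  expect_equal(s$cv, 0)
  s2 <- summary_stats(c(2, 4))
  expect_equal(s2$mean, 3); expect_equal(s2$sd, sqrt(2))
  expect_equal(s2$ci_hi - s2$mean, 1.96 * sqrt(2) / sqrt(2))
  expect_true(is.na(summary_stats(c(-1, 1))$cv))  # zero mean
  # lognormal CV closed form: sigma = 0.6894 -> CV = sqrt(exp(s^2)-1) = 0.78
  set.seed(27)
  x <- rlnorm(1e5, 0, 0.6894)
  expect_equal(summary_stats(x)$cv, sqrt(exp(0.6894^2) - 1), tolerance = 0.02)
  expect_equal(sqrt(exp(0.6894^2) - 1), 0.78, tolerance = 0.002)
})

test_that("run_report assembles the battery and flags missing columns", {
  dir <- small_cohort(n = 250, seed = 31)
  gt <- run_pipeline(dir, quiet = TRUE)$gene_table
  rep_ <- run_report(gt)
  expect_s3_class(rep_, "dga_report")
  expect_named(rep_$responses, c("total_cds_length", "average_cds_length",
                                 "d_all", "rate_per_site", "rate_genic",
                                 "pi_all", "genealogy_length", "mean_maf"))
  r <- rep_$responses$d_all
  expect_equal(nrow(r$regression$coefficients), 8)
  expect_equal(sum(rep_$descriptives$n_by_class), nrow(gt))
  # deterministic given a fixed table
  rep2 <- run_report(gt)
  expect_equal(report_as_table(rep_), report_as_table(rep2))
  tidy <- report_as_table(rep_)
  expect_true(all(c("response", "statistic", "class", "value") %in%
                  names(tidy)))
  expect_error(run_report(gt[, setdiff(names(gt), "pi_all")]),
               "missing column.*pi_all")
})
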