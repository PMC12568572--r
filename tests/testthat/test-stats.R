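make_cohort_df <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = paste0("s", seq_len(n)),
    group = rep(c("HLC", "LLC"), each = n / 2),
    y = rnorm(n, 80, 5),
    age = rnorm(n, 8.4, 0.5),
    sex = sample(c("male", "female"), n, replace = TRUE),
    axl_mm = rnorm(n, 23, 1),
    stringsAsFactors = FALSE
  )
}

test_that("group descriptives: hand values and two-pass oracle", {
  df <- data.frame(group = c("A", "A", "A", "B", "B"),
                   y = c(1, 2, 3, 5, 5))
  d <- describe_by_group(df, "y")
  expect_equal(d$mean, c(2, 5))
  expect_equal(d$sd[1], 1)
  expect_equal(d$sd[2], 0)
  # brute-force two-pass oracle on an arbitrary column
  dfx <- make_cohort_df(20, seed = 4)
  d2 <- describe_by_group(dfx, "y")
  for (gp in c("HLC", "LLC")) {
    x <- dfx$y[dfx$group == gp]
    mu <- sum(x) / length(x)
    s2 <- sum((x - mu)^2) / (length(x) - 1)
    expect_equal(d2$mean[d2$group == gp], mu)
    expect_equal(d2$sd[d2$group == gp], sqrt(s2))
  }
  expect_warning(describe_by_group(data.frame(group = c("A", "B", "B"),
                                              y = 1:3), "y"), "undefined")
})

test_that("t test matches the textbook pooled formula and its edge cases", {
  df <- data.frame(group = rep(c("A", "B"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  tt <- group_t_test(df, "y")
  # hand oracle: pooled variance formula
  sp2 <- (2 * var(1:3) + 2 * var(4:6)) / 4
  t_hand <- (mean(1:3) - mean(4:6)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(unname(tt["t"]), t_hand, tolerance = 1e-12)
  expect_equal(unname(tt["p"]), 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  df0 <- data.frame(group = rep(c("A", "B"), each = 4),
                    y = rep(c(1, 2, 3, 4), 2))
  tt0 <- group_t_test(df0, "y")
  expect_equal(unname(tt0["t"]), 0)
  expect_equal(unname(tt0["p"]), 1)
  # zero pooled variance errors
  expect_error(group_t_test(data.frame(group = rep(c("A", "B"), each = 3),
                                       y = rep(5, 6)), "y"), "variance")
})

test_that("t test p value agrees with the exact permutation null", {
  x <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.1, 2.5, 3.8)
  y <- c(4.9, 5.2, 4.1, 6.0, 5.5, 4.4, 3.6, 4.8)
  df <- data.frame(group = rep(c("A", "B"), each = 8), y = c(x, y))
  p_t <- unname(group_t_test(df, "y")["p"])
  # exact enumeration of all group relabelings (stronger than any
  # Monte-Carlo permutation sample)
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  splits <- combn(16, 8)
  tot <- sum(pooled)
  diffs <- abs(colSums(matrix(pooled[splits], nrow = 8)) / 8 -
                 (tot - colSums(matrix(pooled[splits], nrow = 8))) / 8)
  p_perm <- mean(diffs >= obs - 1e-12)
  expect_lt(abs(p_perm - p_t), 0.02)
})

test_that("chi-square: closed-form 2x2 and z^2 identity", {
  df <- data.frame(group = rep(c("A", "B"), each = 30),
                   s = c(rep("x", 10), rep("y", 20),
                         rep("x", 20), rep("y", 10)))
  cs <- group_chi_square(df, "s")
  expect_equal(unname(cs["chisq"]), 20 / 3, tolerance = 1e-12)
  # chi-square equals the squared two-proportion z statistic
  p1 <- 10 / 30; p2 <- 20 / 30; pp <- 30 / 60
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 30 + 1 / 30))
  expect_equal(unname(cs["chisq"]), z^2, tolerance = 1e-12)
  # equal proportions give exactly zero
  df0 <- data.frame(group = rep(c("A", "B"), each = 10),
                    s = rep(c(rep("x", 5), rep("y", 5)), 2))
  expect_equal(unname(group_chi_square(df0, "s")["chisq"]), 0)
  # empty expected cell errors (a declared but unobserved category)
  dfe <- data.frame(group = rep(c("A", "B"), each = 3),
                    s = factor(rep("x", 6), levels = c("x", "y")))
  expect_error(group_chi_square(dfe, "s"), "expected")
})

test_that("ancova equals the normal-equation oracle to 1e-8", {
  df <- make_cohort_df(12, seed = 2)
  df$y <- df$y - 2 * (df$group == "HLC") + 1.5 * df$age
  a <- ancova(df, "y")
  X <- cbind(1, as.numeric(df$group == "HLC"), df$age,
             as.numeric(df$sex == "male"), df$axl_mm)
  beta <- solve(t(X) %*% X, t(X) %*% df$y)
  expect_lt(max(abs(a$coefficients - beta)) / max(abs(beta)), 1e-8)
})

test_that("with balanced centered covariates ancova collapses to the t test", {
  set.seed(6)
  # both groups carry the same covariate patterns, centered at zero and
  # not collinear with each other
  pat_age <- c(-1.5, -0.5, 0.5, 1.5, -1, 0, 1, 0)
  pat_axl <- c(0.5, -0.5, 0.5, -0.5, 1, -1, 0, 0)
  df <- data.frame(group = rep(c("HLC", "LLC"), each = 8),
                   age = rep(pat_age, 2), axl_mm = rep(pat_axl, 2),
                   y = rnorm(16))
  a <- ancova(df, "y", covariates = c("age", "axl_mm"))
  tt <- group_t_test(df, "y")
  raw_diff <- mean(df$y[df$group == "HLC"]) - mean(df$y[df$group == "LLC"])
  # balanced covariates leave the adjusted difference at the raw difference
  expect_equal(a$adjusted_diff, raw_diff, tolerance = 1e-10)
  # with no covariates the group F test is exactly the pooled t^2
  a0 <- ancova(df, "y", covariates = character(0))
  expect_equal(a0$F, unname(tt["t"])^2, tolerance = 1e-10)
  expect_equal(a0$p, unname(tt["p"]), tolerance = 1e-10)
})

test_that("an outcome linear in age with no group effect adjusts to null", {
  set.seed(9)
  df <- make_cohort_df(200, seed = 10)
  df$y <- 3 * df$age + rnorm(200, 0, 0.5)
  a <- ancova(df, "y")
  expect_lt(abs(a$adjusted_diff), 0.3)
  expect_gt(a$p, 0.001)
})

test_that("adjusted means agree with emmeans on the same model", {
  skip_if_not_installed("emmeans")
  df <- make_cohort_df(40, seed = 3)
  df$sexnum <- as.numeric(df$sex == "male")
  fit <- lm(y ~ group + age + sexnum + axl_mm, data = df)
  # hold the 0/1 sex covariate at its sample mean (emmeans would otherwise
  # average over the two levels with equal weight)
  em <- as.data.frame(emmeans::emmeans(fit, "group",
                                       at = list(sexnum = mean(df$sexnum))))
  a <- ancova(df, "y", covariates = c("age", "sexnum", "axl_mm"))
  expect_equal(unname(a$adjusted_means[em$group]), em$emmean,
               tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the column", {
  df <- make_cohort_df(12, seed = 5)
  df$dup <- df$age
  expect_error(ancova(df, "y", covariates = c("age", "dup")), "dup")
})

test_that("subject-mean mode averages eyes without changing effect signs", {
  g <- generate_cohort(cohort_spec(n_per_group = 60, seed = 21))
  a_eye <- ancova(g$cohort, "vc_um")
  a_sub <- ancova(g$cohort, "vc_um", subject_mean = TRUE)
  expect_equal(sum(a_sub$n_per_group), 120)
  expect_equal(sign(a_sub$adjusted_diff), sign(a_eye$adjusted_diff))
})

test_that("report tables carry the expected shapes and labels", {
  cfg <- default_config()
  cfg$simulate$n_per_group <- 2L
  cfg$simulate$size <- 320L
  cfg$segmentation$segmenter <- "truth"
  res <- run_pipeline(cfg)
  rep <- res$reports
  expect_equal(nrow(rep$global), 9)
  expect_setequal(unique(rep$annulus$scope),
                  c("0.5–1.0 PD", "1.0–1.5 PD",
                    "1.5–2.0 PD", "2.0–2.5 PD"))
  expect_setequal(unique(rep$quadrant$scope),
                  c("Superior", "Nasal", "Inferior", "Temporal"))
  expect_true(all(c("HLC_mean", "HLC_sd", "LLC_mean", "LLC_sd", "p") %in%
                    names(rep$global)))
  # empty cohort: headers only, no failure
  empty <- res$metrics[0, ]
  rep0 <- report_tables(empty)
  expect_equal(nrow(rep0$global), 0)
})
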