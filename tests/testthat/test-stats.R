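test_that("one-way ANOVA matches the sum-of-squares oracle", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, 1.5, tolerance = 1e-10)
  expect_equal(res$df, c(1, 4))
  oracle <- anova_oracle(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(res$p_raw, oracle$p, tolerance = 1e-10)

  set.seed(21)
  for (i in 1:10) {
    groups <- lapply(sample(2:5, sample(2:4, 1), TRUE) + 1,
                     function(n) rnorm(n))
    res <- one_way_anova(groups)
    oracle <- anova_oracle(groups)
    expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
    expect_equal(res$df, oracle$df)
    expect_equal(res$p_raw, oracle$p, tolerance = 1e-10)
  }
})

test_that("identical groups give F = 0 and degenerate inputs error", {
  res <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_raw, 1, tolerance = 1e-12)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "identical")
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2")
})

test_that("two-group ANOVA is the squared equal-variance t statistic", {
  set.seed(22)
  for (i in 1:25) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(3:10, 1))
    f <- one_way_anova(list(x, y))$statistic
    t <- stats::t.test(x, y, var.equal = TRUE)$statistic
    expect_lt(abs(f - t^2), 1e-10)
  }
})

test_that("Holm-Sidak matches the step-down formula in input order", {
  expect_equal(holm_sidak(0.03), 0.03)
  got <- holm_sidak(c(0.01, 0.04, 0.03))
  expect_equal(got, c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2),
               tolerance = 1e-12)
  expect_equal(got, holm_sidak_oracle(c(0.01, 0.04, 0.03)),
               tolerance = 1e-15)
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak is permutation-equivariant, monotone and >= raw", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(holm_sidak(p[perm]), adj[perm], tolerance = 1e-15)
    expect_equal(adj, holm_sidak_oracle(p), tolerance = 1e-15)
  }
})

test_that("paired t-test matches the hand computation on differences", {
  res <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$statistic, -4, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # symmetric differences cancel
  res <- paired_t(c(0, 2), c(1, 1))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_raw, 1, tolerance = 1e-12)
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero")
})

test_that("paired t is antisymmetric under swapping the members", {
  set.seed(24)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(length(x))
    expect_equal(paired_t(x, y)$statistic, -paired_t(y, x)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("linear fit matches the normal equations and the Pearson identity", {
  x <- 1:5
  res <- linear_fit(x, 2 * x + 1)
  expect_equal(res$statistic, 2, tolerance = 1e-12)
  expect_equal(res$extras$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$extras$intercept, 1, tolerance = 1e-12)

  res <- linear_fit(x, rep(3, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$extras$r_squared, 0)

  expect_error(linear_fit(rep(1, 5), 1:5), "constant")

  set.seed(25)
  x <- rnorm(20)
  y <- 1.5 * x + rnorm(20)
  res <- linear_fit(x, y)
  # normal equations solved independently
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$extras$intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$statistic, beta[2], tolerance = 1e-10)
  expect_equal(res$extras$r_squared, cor(x, y)^2, tolerance = 1e-12)
})

test_that("sister CV matches the sd/mean computation and skips singles", {
  meta <- toy_meta()
  calls <- rbind(make_call("cA1", 100, 0.1), make_call("cA2", 100, 0.3))
  expect_warning(res <- sister_cv(calls, meta, "cumulus"), "mB")
  row <- res$per_mouse[res$per_mouse$mouse_id == "mA", ]
  expect_equal(row$cv, sd(c(0.1, 0.3)) / 0.2, tolerance = 1e-12)
  expect_equal(row$cv, 0.7071068, tolerance = 1e-6)
  expect_equal(res$per_age$mean_cv, row$cv)

  # identical sister values give CV 0
  calls <- rbind(make_call("cA1", 100, 0.2), make_call("cA2", 100, 0.2))
  expect_warning(res <- sister_cv(calls, meta, "cumulus"), "mB")
  expect_equal(res$per_mouse$cv[res$per_mouse$mouse_id == "mA"], 0)
})

test_that("D-loop cumulative curves count and decay correctly", {
  ann <- mouse_mt_annotation()
  meta <- toy_meta()
  calls <- rbind(make_call("oA1", 15500, 0.02),
                 make_call("oA1", 15600, 0.05),
                 make_call("oA1", 15700, 0.50),
                 make_call("oA1", 100, 0.80))  # outside the D-loop
  curves <- dloop_cumulative(calls, meta, ann,
                             thresholds = c(0.01, 0.03, 0.2, 0.6))
  oo3 <- curves[curves$age_group == "3wk" & curves$cell_type == "oocyte", ]
  expect_equal(oo3$count, c(3L, 2L, 1L, 0L))
  # all other groups are zero curves
  expect_true(all(curves$count[curves$age_group != "3wk"] == 0L))
  # monotone non-increasing, starting at the total D-loop count
  expect_true(all(diff(oo3$count) <= 0L))
  expect_equal(oo3$count[1L], 3L)
})

test_that("age-group tests pool levels and correct pairwise p-values", {
  meta <- sample_meta(data.frame(
    sample_id = sprintf("s%02d", 1:12),
    mouse_id = rep(sprintf("m%d", 1:6), each = 2),
    age_group = rep(c("3wk", "9wk", "12mo"), each = 4),
    cell_type = rep(c("oocyte", "cumulus"), 6),
    complex_id = rep(sprintf("cx%d", 1:6), each = 2),
    stringsAsFactors = FALSE))
  set.seed(26)
  calls <- do.call(rbind, lapply(meta$sample_id[
    meta$cell_type == "oocyte"], function(s) {
      rbind(make_call(s, 100, runif(1, 0.02, 0.2)),
            make_call(s, 200, runif(1, 0.02, 0.2)))
    }))
  res <- age_group_tests(calls, meta, "oocyte")
  expect_equal(res$omnibus$df[1], 2)
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$p_adjusted,
               holm_sidak_oracle(res$pairwise$p_raw), tolerance = 1e-15)
  # single age group: skipped with warning
  solo <- meta[meta$age_group == "3wk", ]
  solo_calls <- calls[calls$sample_id %in% solo$sample_id, ]
  expect_warning(res <- age_group_tests(solo_calls, sample_meta(solo),
                                        "oocyte"), "skipped")
  expect_null(res$omnibus)
})
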