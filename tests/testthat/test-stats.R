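test_that("the packaged margin table matches its printed rows", {
  df <- load_margin_table()
  expect_equal(nrow(df), 30)
  expect_equal(sum(df$group == "LTP"), 14)
  expect_equal(sum(df$group == "LTP-free"), 16)
  r1 <- df[df$group == "LTP" & df$patient_id == 1, ]
  expect_equal(r1$pct_rigid, 91.30)
  expect_equal(r1$pct_deformed, 4.00)
  expect_equal(r1$cc_rigid, 1.05)
  expect_equal(r1$cc_deformed, 0.25)
  r2 <- df[df$group == "LTP-free" & df$patient_id == 2, ]
  expect_equal(r2$pct_rigid, 100.00)
  expect_equal(r2$pct_deformed, 0.00)
  expect_equal(r2$dta_deformed, 0.61)
  expect_true(all(df$pct_rigid >= 0 & df$pct_rigid <= 100))
  expect_true(all(df$cc_rigid >= 0 & df$cc_deformed >= 0))
})

test_that("Mann-Whitney U: exact enumeration and tie handling", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")

  t <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(t$U, 9 / 2)
  expect_equal(t$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")

  # swapping groups maps U to n_a n_b - U with the same p
  set.seed(7)
  a <- rnorm(8)
  b <- rnorm(11) + 0.5
  f <- mann_whitney_u(a, b)
  g <- mann_whitney_u(b, a)
  expect_equal(f$U + g$U, length(a) * length(b))
  expect_equal(f$p, g$p)
})

test_that("exact and approximate p-values agree with the reference test", {
  set.seed(13)
  a <- round(rnorm(7), 6)
  b <- round(rnorm(9) + 0.8, 6)
  mine <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # tied data goes through the corrected normal approximation
  at <- c(0, 0, 0, 1, 2, 2, 3)
  bt <- c(0, 2, 2, 4, 4, 5, 6, 6)
  mt <- mann_whitney_u(at, bt)
  rt <- suppressWarnings(wilcox.test(at, bt, correct = TRUE))
  expect_equal(mt$U, unname(rt$statistic))
  expect_equal(mt$p, rt$p.value, tolerance = 1e-9)
})

test_that("ROC AUC: separation, ties, symmetry and rank-sum identity", {
  lab <- rep(c("LTP", "LTP-free"), each = 5)
  expect_equal(roc_auc(c(1:5, 11:15), lab), 1)
  expect_equal(roc_auc(rep(2, 10), lab), 0.5)
  expect_error(roc_auc(1:5, rep("LTP", 5)), "both classes")

  set.seed(3)
  sc <- rnorm(10)
  expect_equal(roc_auc(sc, lab) + roc_auc(-sc, lab), 1)

  # AUC equals U / (n_a n_b) on the same data
  u <- mann_whitney_u(sc[lab == "LTP-free"], sc[lab == "LTP"])
  expect_equal(roc_auc(sc, lab), u$U / 25)
})

test_that("group summaries use the population standard deviation", {
  df <- data.frame(group = c("a", "a", "b"), x = c(7, 7, 7))
  s <- summarize_margins(df, "x")
  expect_equal(s$mean[s$group == "pooled"], 7)
  expect_equal(s$sd[s$group == "pooled"], 0)
  expect_equal(s$median[s$group == "pooled"], 7)
  expect_error(summarize_margins(df, "nope"), "unknown column")

  v <- c(1, 2, 3, 4)
  s2 <- summarize_margins(data.frame(x = v), "x", "pooled")
  expect_equal(s2$sd, sqrt(mean((v - mean(v))^2)))
  expect_true(all(s2$min <= s2$median & s2$median <= s2$max))
})

test_that("the full report reproduces the headline statistics", {
  rep <- margin_stats_report()
  pooled <- rep$summaries$pct_rigid
  expect_equal(round(pooled$mean[pooled$group == "pooled"], 2), 19.51)
  expect_equal(round(pooled$sd[pooled$group == "pooled"], 2), 28.26)
  expect_lt(rep$tests$dta_deformed$p, 0.01)
  expect_equal(round(unname(rep$auc["deformed"]), 2), 0.87)
})
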