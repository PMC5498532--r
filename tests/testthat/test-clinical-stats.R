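test_that("product-limit estimate matches hand computation", {
  # all censored: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events: 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2/3, 1/3, 0))
  # mixed censoring: S(1) = 3/4, S(3) = 3/4 * 1/2 = 3/8, S(4) = 0
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  o <- oracle_km(c(1, 2, 3, 4), c(1, 0, 1, 1))
  at <- match(o$time, km2$time)
  expect_equal(km2$survival[at], o$survival)
  expect_equal(o$survival, c(0.75, 0.375, 0))
  # survival and at-risk counts are non-increasing
  expect_true(all(diff(km2$survival) <= 0))
  expect_true(all(diff(km2$n_risk) <= 0))
  expect_error(km_estimate(numeric(), numeric()))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(12)
  for (i in 1:20) {
    tm <- rexp(40)
    km <- km_estimate(tm, rep(1, 40))
    emp <- sapply(km$time, function(t) mean(tm > t))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank agrees with the O/E/variance table and survdiff edge cases", {
  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # hand-tabulated 4-event toy
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  expect_equal(lr$statistic, oracle_logrank(c(1, 3), c(1, 1), c(2, 4), c(1, 1)),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # exchanging group labels leaves the statistic unchanged
  set.seed(3)
  ta <- rexp(25); ea <- rbinom(25, 1, 0.8)
  tb <- rexp(30, 1.7); eb <- rbinom(30, 1, 0.8)
  expect_equal(logrank_test(ta, ea, tb, eb)$statistic,
               logrank_test(tb, eb, ta, ea)$statistic, tolerance = 1e-12)
  # no events anywhere: statistic 0, p 1, warning
  expect_warning(lrn <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
  expect_equal(lrn$p_value, 1)
})

test_that("ROC sweep maximizes Youden's J with the documented tie-breaks", {
  # perfectly separated classes
  r <- roc_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$youden_j, 1)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 10)
  expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)
  # forced sweep example
  r2 <- roc_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r2$cutoff, 2.5)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)
  # J ties (all three cutoffs reach J = 0.5, equally unbalanced): lower cutoff
  r3 <- roc_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r3$cutoff, 1.5)
  expect_error(roc_cutoff(c(1, 2, 3), c(1, 1, 1)), "both label classes")
  expect_error(roc_cutoff(c(1, 1, 2), c(0, 1, 1)), "distinct")
})

test_that("ROC cutoff agrees with pROC's Youden coordinates", {
  skip_if_not_installed("pROC")
  set.seed(88)
  for (i in 1:20) {
    v <- rnorm(60); l <- rbinom(60, 1, plogis(v))
    if (length(unique(l)) < 2) next
    got <- roc_cutoff(v, l)
    roc <- pROC::roc(l, v, quiet = TRUE, direction = "<")
    ref <- pROC::coords(roc, "best", best.method = "youden",
                        ret = c("sensitivity", "specificity"))
    ref_j <- max(ref$sensitivity + ref$specificity - 1)
    expect_equal(got$youden_j, ref_j, tolerance = 1e-10)
  }
})

test_that("J is invariant under strictly increasing transforms and small under permutation", {
  set.seed(14)
  v <- rnorm(80); l <- rbinom(80, 1, plogis(2 * v))
  a <- roc_cutoff(v, l); b <- roc_cutoff(exp(v), l)
  expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
  expect_equal(b$sensitivity, a$sensitivity)
  js <- sapply(1:200, function(i) {
    set.seed(1000 + i)
    roc_cutoff(rnorm(200), sample(rep(0:1, 100)))$youden_j
  })
  expect_gte(mean(js < 0.25), 0.95)
})

test_that("group association reports declared-numerator fold changes with pooled t", {
  v <- c(5, 5, 5, 4, 4, 4)
  g <- rep(c("M0", "M1"), each = 3)
  a <- group_association(v, g, "M0")
  expect_equal(a$fold_change, 1.25)
  expect_equal(unname(a$group_means), c(5, 4))
  expect_equal(a$numerator, "M0")
  # identical groups: fold change 1, p 1
  b <- group_association(rep(2, 6), g, "M1")
  expect_equal(b$fold_change, 1)
  expect_equal(b$test$p_value, 1)
  set.seed(5)
  x <- rnorm(10, 3); y <- rnorm(12, 2.4)
  got <- group_association(c(x, y), rep(c("A", "B"), c(10, 12)), "A")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$test$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(group_association(1:5, c("A", "A", "A", "A", "B"), "A"), "n >= 2")
  expect_error(group_association(1:6, rep("A", 6), "A"), "exactly 2")
})

test_that("planted epithelial markers are lower in M1 tumors", {
  tu <- simulate_bulk_tumors(sim_params(seed = 2))
  cli <- as.data.frame(tu$clinical)
  roles <- tu$truth$gene_role
  g <- names(roles)[roles == "epi_marker"][1]
  a <- group_association(tu$expr$values[g, cli$sample_id], cli$m_status, "M0")
  expect_gt(a$fold_change, 1)
  expect_lt(a$test$p_value, 0.05)
})

test_that("paired association follows the textbook paired t", {
  expect_equal(paired_association(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(21)
  a <- rnorm(5) + 1; b <- a - 1 + rnorm(5, 0, 0.3)
  got <- paired_association(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # swapping the vectors negates t and keeps p
  rev <- paired_association(b, a)
  expect_equal(rev$statistic, -got$statistic)
  expect_equal(rev$p_value, got$p_value)
  # constant non-zero differences are degenerate
  expect_warning(deg <- paired_association(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_equal(deg$p_value, 0)
})

test_that("chi-square matches the closed form, with invariances", {
  even <- chisq_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  got <- chisq_association(matrix(c(20, 5, 5, 20), 2))
  expect_equal(got$statistic, 18.0, tolerance = 1e-12)
  expect_equal(got$df, 1L)
  # collapsing two identical rows preserves the statistic (df drops by one)
  t3 <- matrix(c(10, 10, 4, 8, 8, 9), 3,
               dimnames = list(c("r1", "r2", "r3"), NULL))
  t2 <- rbind(r12 = t3[1, ] + t3[2, ], r3 = t3[3, ])
  expect_equal(chisq_association(t3)$statistic, chisq_association(t2)$statistic,
               tolerance = 1e-10)
  expect_equal(chisq_association(t3)$df - 1L, chisq_association(t2)$df)
  expect_error(chisq_association(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  # 2x2 closed form n(ad-bc)^2 / product of marginals, 100 random tables
  set.seed(33)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    closed <- sum(tab) * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chisq_association(tab)$statistic, closed, tolerance = 1e-10)
    expect_equal(chisq_association(tab)$statistic, oracle_chisq(tab),
                 tolerance = 1e-10)
  }
})

test_that("subtype summaries detect a planted shift and degenerate equality", {
  v <- rep(c(1, 2, 3), times = 4)
  s <- rep(c("A", "B", "C", "D"), each = 3)
  flat <- summarize_by_subtype(v, s)
  expect_equal(flat$test$statistic, 0, tolerance = 1e-12)
  set.seed(9)
  v2 <- c(rnorm(75), rnorm(25, 3))
  s2 <- rep(c("A", "B", "C", "D"), each = 25)
  shifted <- summarize_by_subtype(v2, s2)
  expect_lt(shifted$test$p_value, 0.001)
  expect_equal(shifted$table$n, rep(25L, 4), ignore_attr = TRUE)
  expect_error(summarize_by_subtype(1:5, rep("A", 5)), ">= 2 subtype")
})

test_that("mesenchymal signature peaks in the most mesenchymal pseudo-subtype", {
  tu <- simulate_bulk_tumors(small_params(seed = 19))
  cli <- as.data.frame(tu$clinical)
  roles <- tu$truth$gene_role
  mes <- names(roles)[roles == "mes_marker"]
  sc <- score_signature(tu$expr, mes)
  s <- summarize_by_subtype(sc$score[match(cli$sample_id, sc$sample_id)],
                            cli$subtype)
  expect_equal(s$table$subtype[which.max(s$table$mean)], "CMS4")
  expect_lt(s$test$p_value, 0.001)
})
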