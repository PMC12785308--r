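test_that("Wilson intervals match published-style reference values", {
  expect_equal(round(wilson_ci(8, 24), 3), c(lower = 0.180, upper = 0.533))
  expect_equal(round(wilson_ci(2, 25), 3), c(lower = 0.022, upper = 0.250))
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  expect_equal(wilson_ci(10, 10)[["upper"]], 1)
  expect_error(wilson_ci(2, 0), "n")
  expect_error(wilson_ci(5, 4), "k")
})

test_that("Wilson interval agrees with prop.test and the score-test grid inversion", {
  for (kn in list(c(8, 24), c(2, 25), c(44, 99), c(0, 7), c(7, 7))) {
    ours <- wilson_ci(kn[1], kn[2])
    ref <- suppressWarnings(stats::prop.test(kn[1], kn[2],
                                             correct = FALSE))$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
  for (n in 1:30) for (k in 0:n) {
    ours <- wilson_ci(k, n)
    grid <- oracle_wilson_grid(k, n)
    expect_lt(abs(ours[["lower"]] - grid[1]), 1e-4)
    expect_lt(abs(ours[["upper"]] - grid[2]), 1e-4)
  }
})

test_that("accuracy pools selected cells and excludes missing ones", {
  des <- study_design()
  counts <- c(chatgpt_1 = 4, grok_1 = 4, gemini_1 = 8, claude_1 = 2)
  m <- matrix_from_margins(des, counts, mode = "per_rater")
  ai <- accuracy(m, c("chatgpt", "grok", "gemini", "claude"), label = "ai")
  expect_equal(ai$k, 18)
  expect_equal(ai$n, 99) # the 24-case rater contributes 24, not 25
  expect_equal(ai$p, 18 / 99)
  ones <- correctness_matrix(matrix(1, 2, 3), c("a", "a"))
  res <- accuracy(ones)
  expect_equal(res$p, 1)
  expect_equal(res$upper, 1)
  expect_error(accuracy(m, "nonexistent"), "selector")
})

test_that("Pearson chi-square has no continuity correction and handles degenerate tables", {
  tab <- rbind(c(13, 12), c(10, 15), c(15, 9), c(6, 19))
  res <- pearson_chi2(tab)
  expect_equal(res$df, 3)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$p_value, 0.04245838, tolerance = 1e-6)
  same <- rbind(c(10, 10), c(10, 10))
  expect_equal(pearson_chi2(same)$statistic, 0)
  expect_equal(pearson_chi2(same)$p_value, 1)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "marginal")
  # on a 2x2, the statistic equals the squared two-proportion z statistic
  t22 <- rbind(c(30, 20), c(18, 32))
  p1 <- 30 / 50; p2 <- 18 / 50; pp <- 48 / 100
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 50 + 1 / 50))
  expect_equal(pearson_chi2(t22)$statistic, z^2, tolerance = 1e-10)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(rbind(c(0, 5), c(5, 0))), 2 / 252,
               tolerance = 1e-9)
  tab <- rbind(c(4, 2), c(1, 5))
  expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)))
  # exhaustive over all tables with total <= 16, seeded sample up to 20
  small <- expand.grid(a = 0:16, b = 0:16, c = 0:16, d = 0:16)
  small <- small[rowSums(small) <= 16 & rowSums(small) >= 1, ]
  large <- trichobench:::with_seed(13, {
    out <- list()
    while (length(out) < 300) {
      t4 <- as.integer(stats::rmultinom(1, sample(17:20, 1), rep(0.25, 4)))
      out[[length(out) + 1]] <- t4
    }
    do.call(rbind, out)
  })
  colnames(large) <- c("a", "b", "c", "d")
  tables <- rbind(as.matrix(small), large)
  for (i in seq_len(nrow(tables))) {
    tab <- matrix(tables[i, ], 2, 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  for (rep_i in 1:25) {
    p <- trichobench:::with_seed(rep_i, stats::runif(sample(2:8, 1)))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("compare_groups selects the right test and gates the post hoc step", {
  # identical groups: statistic 0, p = 1, no post hoc
  m <- correctness_matrix(rbind(rep(c(1, 0), 10), rep(c(1, 0), 10)), c("a", "b"))
  res <- compare_groups(m)
  expect_equal(res$p_value, 1)
  expect_null(res$post_hoc)
  # three clearly different groups trigger Holm-adjusted pairwise tests
  m3 <- correctness_matrix(rbind(c(rep(1, 18), rep(0, 2)),
                                 c(rep(1, 10), rep(0, 10)),
                                 c(rep(1, 2), rep(0, 18))),
                           c("hi", "mid", "lo"))
  res3 <- compare_groups(m3)
  expect_lt(res3$p_value, 0.05)
  expect_equal(nrow(res3$post_hoc), 3)
  expect_true(all(res3$post_hoc$p_holm >= res3$post_hoc$p_raw))
  # small counts fall back to Fisher
  m2 <- correctness_matrix(rbind(c(1, 1, 1, 0), c(0, 0, 0, 0)), c("a", "b"))
  expect_equal(compare_groups(m2)$test, "fisher")
  expect_error(compare_groups(correctness_matrix(matrix(1, 1, 4), "a")), "2 groups")
})

test_that("null rejection rate of compare_groups is calibrated near 5%", {
  reps <- 2000
  rejections <- trichobench:::with_seed(2024, {
    sum(vapply(seq_len(reps), function(i) {
      m <- correctness_matrix(rbind(stats::rbinom(100, 1, 0.5),
                                    stats::rbinom(100, 1, 0.5)),
                              c("g1", "g2"))
      compare_groups(m)$p_value < 0.05
    }, logical(1)))
  })
  rate <- rejections / reps
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("accuracy_table lays out pooled and per-group rows in percent", {
  des <- study_design()
  counts <- c(resident = 61, board_certified = 51, expert = 106,
              chatgpt = 4, grok = 4, gemini = 8, claude = 2)
  m <- matrix_from_margins(des, counts, mode = "per_group")
  tab <- accuracy_table(m, mode = "SD",
                        pooled = list(dermatologists = c("resident",
                                                         "board_certified",
                                                         "expert")))
  expect_equal(tab$pct[tab$group == "dermatologists"], 100 * 218 / 375)
  expect_equal(tab$k[tab$group == "expert"], 106)
  expect_true(all(tab$ci_lo <= tab$pct & tab$pct <= tab$ci_hi))
})
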