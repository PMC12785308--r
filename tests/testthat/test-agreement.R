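test_that("perfect agreement gives AC1 = 1 and the worked 2x4 example evaluates exactly", {
  perfect <- correctness_matrix(rbind(c(1, 0, 1, 1), c(1, 0, 1, 1),
                                      c(1, 0, 1, 1)), rep("g", 3))
  res <- gwet_ac1(perfect)
  expect_equal(res$p_a, 1)
  expect_equal(res$ac1, 1)
  expect_equal(res$category, "very good")

  hand <- correctness_matrix(rbind(c(1, 1, 0, 0), c(1, 0, 0, 0)), c("a", "b"))
  res2 <- gwet_ac1(hand)
  expect_equal(res2$p_a, 0.75)
  expect_equal(res2$pi, 0.375)
  expect_equal(res2$p_e, 0.46875)
  expect_equal(res2$ac1, 0.529412, tolerance = 1e-6)
})

test_that("items rated by fewer than two raters are excluded without effect", {
  m <- rbind(c(1, 0, 1, NA), c(1, 1, 0, NA), c(NA, 0, 1, 1))
  full <- gwet_ac1(correctness_matrix(m, c("a", "b", "c")))
  dropped <- gwet_ac1(correctness_matrix(m[, 1:3], c("a", "b", "c")))
  expect_equal(full$ac1, dropped$ac1)
  expect_equal(full$n_items, 3)
  expect_error(gwet_ac1(correctness_matrix(matrix(c(1, NA, NA, 1), 2, 2),
                                           c("a", "b"))), "2 items")
})

test_that("AC1 matches an independent rater-pair enumeration to 1e-12", {
  for (rep_i in 1:40) {
    m <- trichobench:::with_seed(rep_i, {
      mm <- matrix(stats::rbinom(5 * 12, 1, stats::runif(1, 0.2, 0.8)), 5, 12)
      mm[stats::runif(length(mm)) < 0.1] <- NA
      mm
    })
    r_i <- colSums(!is.na(m))
    if (sum(r_i >= 2) < 2) next
    ours <- gwet_ac1(correctness_matrix(m, paste0("g", 1:5)))$ac1
    expect_equal(ours, oracle_ac1(m), tolerance = 1e-12)
  }
})

test_that("AC1 is invariant to swapping the 0/1 labels", {
  for (rep_i in 1:20) {
    m <- trichobench:::with_seed(100 + rep_i,
                                 matrix(stats::rbinom(4 * 15, 1, 0.7), 4, 15))
    a <- gwet_ac1(correctness_matrix(m, paste0("g", 1:4)))$ac1
    b <- gwet_ac1(correctness_matrix(1 - m, paste0("g", 1:4)))$ac1
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("at prevalence 1/2 with two raters AC1 reduces to (a - 1/2) / (1/2)", {
  # pair each item with its 0/1 complement so the mean prevalence is exactly 0.5
  base <- rbind(c(1, 1, 0, 1, 0, 0), c(1, 0, 0, 1, 1, 0))
  m <- cbind(base, 1 - base)
  res <- gwet_ac1(correctness_matrix(m, c("r1", "r2")))
  expect_equal(res$pi, 0.5)
  expect_equal(res$ac1, (res$p_a - 0.5) / 0.5, tolerance = 1e-12)
})

test_that("jackknife SE shrinks by ~1/sqrt(2) when every item is duplicated", {
  m <- trichobench:::with_seed(5, matrix(stats::rbinom(4 * 20, 1, 0.6), 4, 20))
  single <- gwet_ac1(correctness_matrix(m, paste0("g", 1:4)))
  doubled <- gwet_ac1(correctness_matrix(cbind(m, m), paste0("g", 1:4)))
  expect_equal(doubled$ac1, single$ac1, tolerance = 1e-12)
  expect_equal(doubled$se / single$se, 1 / sqrt(2), tolerance = 0.1)
})

test_that("agreement bands map values to the stated categories", {
  expect_equal(categorize_ac1(0.70), "good")
  expect_equal(categorize_ac1(-0.1), "poor")
  expect_equal(categorize_ac1(0.21), "fair")
  expect_equal(categorize_ac1(c(0.05, 0.20, 0.405, 0.61, 0.81, 1)),
               c("slight", "slight", "moderate", "good", "very good", "very good"))
  expect_error(categorize_ac1(1.2), "exceed")
})

test_that("between-group agreement equals AC1 on the majority-vote vectors", {
  m <- trichobench:::with_seed(17, matrix(stats::rbinom(9 * 20, 1, 0.6), 9, 20))
  groups <- rep(c("a", "b", "c"), each = 3)
  cm <- correctness_matrix(m, groups)
  res <- between_group_agreement(cm)
  votes <- t(sapply(c("a", "b", "c"), function(g)
    as.integer(colSums(m[groups == g, ] == 1) > colSums(m[groups == g, ] == 0))))
  direct <- gwet_ac1(correctness_matrix(votes, c("a", "b", "c")))
  expect_equal(res$ac1, direct$ac1, tolerance = 1e-12)

  unanimous <- correctness_matrix(rbind(m[1, ], m[1, ], m[1, ], m[1, ]),
                                  c("a", "a", "b", "b"))
  expect_equal(between_group_agreement(unanimous)$ac1, 1)
  opposite <- correctness_matrix(rbind(rep(1, 10), rep(0, 10)), c("a", "b"))
  expect_equal(between_group_agreement(opposite)$p_a, 0)
})

test_that("agreement_table mirrors the reliability-table layout", {
  des <- study_design()
  m <- simulate_responses(des, response_model(
    stats::setNames(c(0.5, 0.5, 1.5, -1, -1, 0, -2), names(des$groups)), 1),
    seed = 8)
  tab <- agreement_table(m, mode = "SD",
                         pooled = list(dermatologists = c("resident",
                                                          "board_certified",
                                                          "expert"),
                                       ai = c("chatgpt", "grok", "gemini",
                                              "claude")),
                         between = list(dermatologists_vs_ai =
                                          trichobench:::derm_vs_ai_grouping()))
  expect_true(all(c("dermatologists", "ai", "resident", "expert",
                    "dermatologists_vs_ai") %in% tab$group))
  expect_true(all(tab$ci_lo <= tab$ac1 & tab$ac1 <= tab$ci_hi))
  expect_true(all(tab$ac1 <= 1))
  expect_equal(tab$category, categorize_ac1(tab$ac1))
})
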