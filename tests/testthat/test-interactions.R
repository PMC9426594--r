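test_that("multiplicative expectation is the plain product", {
  expect_equal(expected_growth(1.0, 1.0), 1.0)
  expect_equal(expected_growth(0.8, 0.5), 0.40)
  expect_equal(expected_growth(0.0, 0.7), 0.0)
  expect_equal(expected_growth(0.8, 0.5), expected_growth(0.5, 0.8))
  expect_error(expected_growth(-0.1, 0.5), ">= 0")
})

test_that("propagated sigma follows the relative-variance sum", {
  expect_equal(propagated_sigma(0.8, 0, 0.5, 0), 0)
  expect_equal(propagated_sigma(0.8, 0.1, 0.5, 0.05),
               0.4 * sqrt(0.125^2 + 0.1^2))
  expect_equal(propagated_sigma(0.8, 0.1, 0.5, 0.05),
               propagated_sigma(0.5, 0.05, 0.8, 0.1))  # symmetry
  expect_equal(propagated_sigma(0, 0, 0.7, 0.1), 0)
  expect_error(propagated_sigma(0, 0.1, 0.7, 0.1), "zero growth")
  expect_error(propagated_sigma(0.5, -0.1, 0.7, 0.1), ">= 0")
})

test_that("propagated sigma agrees with a Monte-Carlo product SD at small CV", {
  set.seed(7)
  n <- 2e5
  ga <- 0.8; sa <- 0.016  # 2% CV
  gb <- 0.5; sb <- 0.005  # 1% CV
  prod_sd <- sd(rnorm(n, ga, sa) * rnorm(n, gb, sb))
  expect_equal(propagated_sigma(ga, sa, gb, sb), prod_sd,
               tolerance = 0.02)
})

test_that("Welch test matches the textbook formulas and t.test", {
  # hand evaluation: t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2),
  # df by Welch-Satterthwaite
  w <- welch_test(0.5, 0.05, 4, 0.4, 0.06403, 3)
  se2 <- 0.05^2 / 4 + 0.06403^2 / 3
  expect_equal(w$t, 0.1 / sqrt(se2))
  expect_equal(w$t, 2.24, tolerance = 0.01)
  expect_equal(w$df,
               se2^2 / ((0.05^2 / 4)^2 / 3 + (0.06403^2 / 3)^2 / 2))
  expect_equal(w$df, 3.7, tolerance = 0.03)
  expect_equal(w$p, 2 * pt(-abs(w$t), w$df))

  # equal means -> t = 0, p = 1 whatever the sds
  w0 <- welch_test(0.7, 0.2, 5, 0.7, 0.01, 3)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # doubling both sds halves |t|
  w1 <- welch_test(0.5, 0.05, 4, 0.4, 0.064, 3)
  w2 <- welch_test(0.5, 0.10, 4, 0.4, 0.128, 3)
  expect_equal(w2$t, w1$t / 2)

  # degenerate: both sds zero
  expect_equal(welch_test(1, 0, 3, 1, 0, 3)$p, 1)
  expect_equal(welch_test(1, 0, 3, 2, 0, 3)$p, 0)
  expect_error(welch_test(1, 0.1, 1, 2, 0.1, 3), ">= 2")

  # cross-check against stats::t.test on raw samples
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    ref <- t.test(x, y)
    ours <- welch_test(mean(x), sd(x), length(x),
                       mean(y), sd(y), length(y))
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # NA entries are excluded from the family and returned as NA
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))

  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))                   # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= 0))   # monotone in p
  }
})

test_that("null records produce no significant interaction calls", {
  # observed == expected exactly for every pair
  genes <- c("a", "b", "c")
  summaries <- dplyr::bind_rows(
    tibble::tibble(strain_id = "WT", condition = "c1", growth = 1,
                   sd = 0.05, n = 4L),
    tibble::tibble(strain_id = genes, condition = "c1",
                   growth = c(0.9, 0.8, 0.7), sd = 0.05, n = 4L),
    tibble::tibble(strain_id = c("a:b", "a:c", "b:c"), condition = "c1",
                   growth = c(0.72, 0.63, 0.56), sd = 0.05, n = 4L))
  res <- call_interactions(summaries, make_strains(genes))
  rec <- tidy(res)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$class == "none"))
  expect_equal(rec$expected, rec$observed)
  expect_equal(glance(res)$n_significant, 0L)
})

test_that("records are bookkept per pair x condition with a joint BH family", {
  genes <- c("a", "b")
  summaries <- tidyr::expand_grid(
    strain_id = c("WT", "a", "b", "a:b"),
    condition = c("c1", "c2")) |>
    dplyr::mutate(growth = rep(c(1, 0.9, 0.8, 0.5), each = 2),
                  sd = 0.04, n = 4L)
  # second pair via a second panel gene set: use 3 genes, 2 pairs present
  genes <- c("a", "b", "c")
  summaries <- dplyr::bind_rows(
    summaries,
    tidyr::expand_grid(strain_id = c("c", "a:c"),
                       condition = c("c1", "c2")) |>
      dplyr::mutate(growth = rep(c(0.7, 0.35), each = 2),
                    sd = 0.04, n = 4L))
  res <- call_interactions(summaries, make_strains(genes))
  rec <- tidy(res)
  expect_equal(nrow(rec), 4)  # 2 pairs x 2 conditions ("b:c" not screened)
  expect_equal(rec$q_value, bh_adjust(rec$p_value))  # family m = 4
  # symmetry: statistics identical if the pair's genes swap roles
  w1 <- welch_test(0.5, 0.04, 4, 0.9 * 0.8,
                   propagated_sigma(0.9, 0.04, 0.8, 0.04), 4)
  i <- rec$strain_id == "a:b" & rec$condition == "c1"
  expect_equal(rec$t_stat[i], w1$t)
  expect_equal(rec$expected[i], 0.72)
})

test_that("untestable records are flagged and excluded from the BH family", {
  genes <- c("a", "b", "c")
  summaries <- dplyr::bind_rows(
    tibble::tibble(strain_id = c("WT", "a", "b"), condition = "c1",
                   growth = c(1, 0.9, 0.8), sd = 0.05, n = 4L),
    # single mutant "c" missing entirely; a:c present
    tibble::tibble(strain_id = c("a:b", "a:c"), condition = "c1",
                   growth = c(0.3, 0.4), sd = 0.05, n = 4L),
    # n = 1 double: untestable
    tibble::tibble(strain_id = "b:c", condition = "c1",
                   growth = 0.5, sd = NA_real_, n = 1L))
  res <- call_interactions(summaries, make_strains(genes))
  rec <- tidy(res)
  expect_equal(sum(rec$testable), 1)
  ut <- rec[!rec$testable, ]
  expect_true(all(is.na(ut$p_value)))
  expect_true(all(is.na(ut$q_value)))
  expect_true(all(ut$class == "none"))
  # BH family is only the testable record
  expect_equal(rec$q_value[rec$testable], rec$p_value[rec$testable])
})

test_that("a strongly enhancing planted pair is recovered from simulation", {
  ints <- tibble::tibble(gene_a = "g01", gene_b = "g02", condition = "c1",
                         epsilon = -0.6)
  res <- simulate_and_call(genes = 8, conditions = "c1",
                           interactions = ints, noise_cv = 0.05, seed = 42)
  rec <- tidy(res$interactions)
  hit <- rec[rec$strain_id == "g01:g02", ]
  expect_equal(hit$class, "enhancing")
  expect_lt(hit$q_value, 0.05)
  expect_equal(hit$deviation_ratio, 0.4, tolerance = 0.1)
})
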