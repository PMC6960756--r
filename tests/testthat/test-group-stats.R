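test_that("keyword t-test matches closed form and a permutation oracle", {
  # identical groups: no difference
  x <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  expect_equal(keyword_ttest(x, x)$p_value, 1, tolerance = 1e-12)

  # fully separated groups
  set.seed(1)
  a <- rnorm(20, 0, 1e-4)
  b <- 1 + rnorm(20, 0, 1e-4)
  expect_lt(keyword_ttest(a, b)$p_value, 1e-6)

  # toy groups against the textbook closed form, evaluated independently
  A <- c(1, 2, 3, 4); B <- c(3, 4, 5, 6)
  tt <- keyword_ttest(A, B)
  se <- sqrt(var(A) / 4 + var(B) / 4)
  t_expected <- (mean(A) - mean(B)) / se
  df_expected <- se^4 / ((var(A) / 4)^2 / 3 + (var(B) / 4)^2 / 3)
  p_expected <- 2 * stats::pt(-abs(t_expected), df_expected)
  expect_equal(tt$t_statistic, t_expected)
  expect_equal(tt$p_value, p_expected)

  # exhaustive permutation oracle: all 70 relabellings of the 8 values,
  # mid-p convention (ties at the observed statistic count half), the
  # appropriate comparison for so discrete a permutation distribution
  pooled <- c(A, B)
  combs <- utils::combn(8, 4)
  perm_stats <- apply(combs, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  obs <- abs(mean(A) - mean(B))
  p_perm <- mean(perm_stats > obs + 1e-12) +
    0.5 * mean(abs(perm_stats - obs) <= 1e-12)
  expect_lt(abs(tt$p_value - p_perm), 0.03)

  expect_error(keyword_ttest(1, c(1, 2)), class = "invalid_argument")
  expect_error(keyword_ttest(c(1, NA), c(1, 2)), class = "invalid_argument")
  expect_error(keyword_ttest(c(1, 1), c(1, 1)), class = "degenerate_groups")
})

test_that("significance tiers apply strict thresholds", {
  expect_equal(significance_tier(6.88e-8), "p<0.01")
  expect_equal(significance_tier(1.02e-1), "ns")
  expect_equal(significance_tier(0.05), "ns")
  expect_equal(significance_tier(0.01), "p<0.05")
  expect_equal(significance_tier(0.049999), "p<0.05")

  # pure monotone step function of p
  ps <- sort(c(10^runif(50, -9, 0), 0.01, 0.05))
  tiers <- significance_tier(ps)
  ranks <- c("p<0.01" = 1, "p<0.05" = 2, "ns" = 3)[tiers]
  expect_false(is.unsorted(ranks))

  expect_error(significance_tier(0), class = "invalid_argument")
  expect_error(significance_tier(1.2), class = "invalid_argument")
})

test_that("group comparison produces the full 9 x 2 grid", {
  cfg <- sim_config(seed = 8, n_subjects_per_group = 20,
                    valence_effect_size = 1.2)
  rep <- compare_groups(simulate_response_tables(cfg))
  expect_equal(nrow(rep), 18)
  expect_setequal(unique(rep$axis), c("valence", "arousal"))
  expect_equal(unname(table(rep$axis)), c(9L, 9L), ignore_attr = TRUE)
  expect_true(all(rep$n_photograph == 20 & rep$n_artwork == 20))
  expect_true(all(rep$tier == significance_tier(rep$p_value)))
  m <- report_matrix(rep)
  expect_equal(dim(m), c(2, 9))

  only_ph <- simulate_response_tables(cfg)
  only_ph <- only_ph[only_ph$group == "photograph", ]
  expect_error(compare_groups(only_ph), class = "invalid_argument")
})

test_that("null p-values are uniform", {
  cfg <- sim_config(seed = 17, n_subjects_per_group = 20)
  ps <- numeric(0)
  for (r in 1:400) {
    cfg$seed <- substream_seed(17, "nulluniform", r)
    tab <- simulate_response_tables(cfg)
    rep <- compare_groups(tab)
    ps <- c(ps, rep$p_value)
  }
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
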