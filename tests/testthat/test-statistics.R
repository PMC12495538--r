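# minimal hand-built cohort: ns subjects, all 17 sites, 1 frequency per probe
toy_cohort <- function(values_by_subject, freq = 20e9, probe = "WR42") {
  sites <- site_classes()
  all_sites <- data.frame(site_code = c(sites$thin, sites$thick),
                          sc_class = rep(c("thin", "thick"),
                                         c(length(sites$thin),
                                           length(sites$thick))))
  do.call(rbind, lapply(seq_along(values_by_subject), function(i) {
    data.frame(subject_id = sprintf("S%02d", i),
               site_code = rep(all_sites$site_code, each = 3),
               sc_class = rep(all_sites$sc_class, each = 3),
               probe = probe, frequency = freq,
               repeat_index = rep(1:3, nrow(all_sites)),
               s11_db = values_by_subject[i])
  }))
}

test_that("aggregation follows repeat -> site -> subject order with closed forms", {
  coh <- toy_cohort(c(-3, -4))
  sv <- subject_values(coh)
  # all repeats and sites identical: subject value equals the constant
  expect_equal(sort(unique(sv$s11_db)), c(-4, -3))
  sm <- summarize_cohort(coh)
  thin <- sm[sm$sc_class == "thin", ]
  expect_equal(thin$mean_db, -3.5)
  expect_equal(thin$sd_db, sqrt(0.5), tolerance = 1e-12)
  expect_equal(thin$n, 2L)

  # missing repeat: strict errors, "available" averages what is there
  broken <- coh[-1, ]
  expect_error(subject_values(broken), "strict repeat policy")
  expect_silent(subject_values(broken, repeat_policy = "available"))

  # repeat averaging really happens first
  coh2 <- toy_cohort(0)
  coh2$s11_db <- ifelse(coh2$repeat_index == 1, -3.3,
                        ifelse(coh2$repeat_index == 2, -3.0, -2.7))
  expect_equal(unique(subject_values(coh2)$s11_db), -3.0)

  # record shuffling does not change the summary
  coh3 <- toy_cohort(c(-2.5, -3.5, -4.5))
  sm1 <- summarize_cohort(coh3)
  sm2 <- summarize_cohort(coh3[sample(nrow(coh3)), ])
  expect_equal(sm1, sm2)

  # site labels inconsistent with the taxonomy are rejected
  bad <- coh
  bad$sc_class[bad$site_code == "1F"] <- "thick"
  expect_error(subject_values(bad), "inconsistent")
})

test_that("normality wrapper guards degenerate samples and detects bimodality", {
  expect_error(test_normality(c(1, 2)), "at least 3")
  expect_error(test_normality(rep(1, 10)), "degenerate")
  set.seed(11)
  x <- rnorm(44)
  expect_equal(test_normality(x), shapiro.test(x)$p.value)
  # strongly separated mixture at n = 44 is decisively rejected
  set.seed(12)
  mix <- c(rnorm(33, 0, 0.2), rnorm(11, -1.5, 0.2))
  expect_lt(test_normality(mix), 0.01)
})

test_that("paired comparison matches the hand-computed t statistic", {
  thin <- c(1.0, 2.0, 3.0)
  thick <- c(0.5, 1.2, 2.4)
  r <- paired_diff_test(thin, thick)
  d <- thin - thick
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$mean_diff_db, mean(d))
  expect_equal(r$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)

  same <- paired_diff_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff_db, 0)
  expect_equal(same$p, 1)
  cst <- paired_diff_test(c(1, 2, 3), c(0.6, 1.6, 2.6))
  expect_equal(cst$mean_diff_db, 0.4)
  expect_equal(cst$ci95_lo, 0.4)
  expect_equal(cst$ci95_hi, 0.4)
  expect_equal(cst$p, 0)

  # pair-order permutation invariance
  set.seed(13)
  a <- rnorm(10); b <- rnorm(10)
  o <- sample(10)
  expect_equal(paired_diff_test(a, b)$p, paired_diff_test(a[o], b[o])$p)
  expect_error(paired_diff_test(1:3, 1:4), "paired")
})

test_that("frequency-mean normalization is centering, idempotent, shift-preserving", {
  coh <- generate_cohort(cohort_config(), seed = 21)
  sv <- subject_values(coh$data)
  res <- normalize_by_frequency_mean(sv)
  agg <- aggregate(s11_db ~ sc_class + probe + frequency, res, mean)
  expect_lt(max(abs(agg$s11_db)), 1e-12)
  res2 <- normalize_by_frequency_mean(res)
  expect_equal(res2$s11_db, res$s11_db)

  # a group shift survives normalization as a between-group difference
  shifted <- sv
  males <- shifted$sex == "M"
  shifted$s11_db[males] <- shifted$s11_db[males] + 0.3
  r <- normalize_by_frequency_mean(shifted)
  g <- group_comparison(r[r$sc_class == "thin", ], "sex")
  g0 <- group_comparison(normalize_by_frequency_mean(sv)[sv$sc_class == "thin", ],
                         "sex")
  expect_equal(abs(g$mean_diff_db - g0$mean_diff_db), rep(0.3, nrow(g)),
               tolerance = 1e-9)
})

test_that("group comparison reports pooled t and Bartlett results", {
  set.seed(31)
  df <- data.frame(sc_class = "thin", probe = "WR42", frequency = 20e9,
                   sex = rep(c("F", "M"), each = 12),
                   s11_db = c(rnorm(12, 0, 0.2), rnorm(12, 0, 0.2)))
  r <- group_comparison(df, "sex")
  expect_true(r$p_t >= 0 && r$p_t <= 1)
  expect_true(r$p_bartlett >= 0 && r$p_bartlett <= 1)

  # identical groups: both tests are maximally compatible
  df2 <- df
  df2$s11_db <- rep(df$s11_db[1:12], 2)
  r2 <- group_comparison(df2, "sex")
  expect_equal(r2$p_t, 1)
  expect_equal(r2$p_bartlett, 1)
  expect_equal(r2$mean_diff_db, 0)

  # grossly unequal variances are flagged by Bartlett
  df3 <- df
  df3$s11_db[df3$sex == "M"] <- rnorm(12, 0, 2)
  expect_lt(group_comparison(df3, "sex")$p_bartlett, 0.01)
})

test_that("coverage curves subtract k standard deviations with the field labels", {
  sm <- data.frame(sc_class = "thin", probe = "WR42",
                   frequency = c(20e9, 25e9), mean_db = c(-2.7, -2.9),
                   sd_db = c(0.2, 0.25), n = 44L)
  c0 <- coverage_curves(sm, 0)
  expect_equal(c0$curve_db, sm$mean_db)
  expect_equal(c0$label[1], "mean")
  c1 <- coverage_curves(sm, 1)
  expect_equal(c1$curve_db, sm$mean_db - sm$sd_db)
  expect_equal(c1$label[1], "68% coverage")
  c2 <- coverage_curves(sm, 2)
  expect_equal(c2$curve_db, sm$mean_db - 2 * sm$sd_db)
  expect_equal(c2$label[1], "95% coverage")
  smz <- sm; smz$sd_db <- 0
  expect_equal(coverage_curves(smz, 2)$curve_db, coverage_curves(smz, 0)$curve_db)
})
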