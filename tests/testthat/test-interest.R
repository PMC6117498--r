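test_that("ratio thresholding floors noise and nothing else", {
  theta <- matrix(c(0.245, 0.10, 0.5, 1 / 9), 2, 2)
  out <- topic_ratios(theta)
  expect_equal(out[1, 1], 0.245)   # above the floor, untouched
  expect_equal(out[2, 1], 0)       # 0.10 < 1/9, zeroed
  expect_equal(out[2, 2], 1 / 9)   # at the floor, kept
  expect_equal(topic_ratios(theta, floor = 0), theta)
  expect_error(topic_ratios(theta, floor = 1.5), "\\[0, 1\\]")

  # thresholding never increases an entry; containment is non-increasing
  # in the floor
  set.seed(23)
  th <- matrix(runif(60), 10, 6)
  th <- th / rowSums(th)
  floors <- c(0, 0.05, 1 / 9, 0.2, 0.5)
  expect_true(all(topic_ratios(th, 0.2) <= th))
  cont <- sapply(floors, function(f) containment_fraction(topic_ratios(th, f)))
  expect_true(all(diff(t(cont)) <= 1e-12))
})

test_that("containment fractions count documents containing each topic", {
  m <- cbind(c(0, 0, 0), c(0.3, 0.2, 0.4), c(0.5, 0, 0.2))
  expect_equal(unname(containment_fraction(m)), c(0, 1, 2 / 3))
  expect_error(containment_fraction(m, group = rep(FALSE, 3)), "empty group")

  set.seed(24)
  mm <- matrix(sample(c(0, 0.3, 0.6), 40, TRUE), 8, 5)
  oracle <- apply(mm, 2, function(col) sum(col > 0) / length(col))
  expect_equal(unname(containment_fraction(mm)), oracle)
})

test_that("Cohen's d matches the pooled-SD textbook formula on raw data", {
  expect_equal(cohens_d(1, 1, 50, 0, 1, 50), 1)
  expect_equal(cohens_d(0.4, 0.2, 30, 0.4, 0.2, 30), 0)
  expect_true(is.na(cohens_d(1, 0, 10, 1, 0, 10)))
  expect_error(cohens_d(1, 1, 1, 0, 1, 50), "n >= 2")

  set.seed(25)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 2))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 2))
    # independent oracle, computed from raw data
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    want <- (mean(x) - mean(y)) / sp
    got <- cohens_d(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Welch and pooled t match the reference implementation", {
  set.seed(26)
  for (i in 1:20) {
    x <- rnorm(sample(5:60, 1), runif(1, -1, 1), runif(1, .2, 3))
    y <- rnorm(sample(5:60, 1), runif(1, -1, 1), runif(1, .2, 3))
    for (ve in c(FALSE, TRUE)) {
      ref <- stats::t.test(x, y, var.equal = ve)
      got <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                     var_equal = ve)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
  same <- welch_t(0.3, 0.1, 20, 0.3, 0.1, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(is.na(welch_t(1, 0, 5, 2, 0, 5)$t))
  # sign(t) follows sign(delta_u)
  a <- welch_t(0.5, 0.2, 20, 0.3, 0.2, 20)
  b <- welch_t(0.3, 0.2, 20, 0.5, 0.2, 20)
  expect_gt(a$t, 0)
  expect_lt(b$t, 0)
})

test_that("printed-summary t recovery reduces correctly at unit pooled SD", {
  # delta_u = d means s_pooled = 1; with n1 = n2 = 2, t = delta_u
  expect_equal(t_from_printed_summary(0.7, 0.7, 2, 2), 0.7)
  expect_error(t_from_printed_summary(0.5, 0, 10, 10), "nonzero")
})

test_that("effect-size bands follow the published cut-points", {
  expect_equal(as.character(effect_band(0.005)), "small")
  expect_equal(as.character(effect_band(0.25)), "large")
  expect_equal(as.character(effect_band(-1.55)), "huge")
  expect_equal(as.character(effect_band(2.7)), "huge")
  # boundaries belong to the upper band
  expect_equal(as.character(effect_band(c(0.01, 0.20, 0.50, 0.80))),
               c("medium", "large", "very large", "huge"))
})

test_that("group comparison recovers planted effects and stays null on none", {
  set.seed(27)
  n <- 2000
  grp <- rep(c("g1", "g2"), each = n)
  base <- matrix(pmax(rnorm(2 * n * 4, 0.25, 0.12), 0), 2 * n, 4)
  shifted <- base
  shifted[grp == "g1", 2] <- shifted[grp == "g1", 2] + 0.1  # planted effect
  colnames(shifted) <- paste0("T", 1:4)
  cmp <- compare_groups(topic_ratios(shifted, floor = 0), grp)
  expect_equal(nrow(cmp), 4)
  expect_gt(cmp$delta_u[2], 0)
  expect_gt(cmp$t[2], 0)
  expect_lt(cmp$p_value[2], 0.001)
  expect_equal(sign(cmp$cohen_d), sign(cmp$delta_u))

  # identical groups by construction: no band above medium at n = 2000
  colnames(base) <- paste0("T", 1:4)
  null_cmp <- compare_groups(topic_ratios(base, floor = 0), grp)
  expect_true(all(null_cmp$band <= "medium"))

  # zero variance in both groups marks that topic undefined, others fine
  degen <- cbind(shifted[, 1:2], T5 = rep(0.4, 2 * n))
  cmp2 <- compare_groups(degen, grp)
  expect_true(is.na(cmp2$t[3]))
  expect_false(anyNA(cmp2$t[1:2]))

  # NA group rows are excluded, not misassigned
  grp_na <- grp
  grp_na[1:10] <- NA
  cmp3 <- compare_groups(shifted, grp_na)
  expect_equal(cmp3$n1[1], n - 10)
  expect_error(compare_groups(shifted, rep("g1", 2 * n)), "two groups")
})

test_that("mine_interests chains theta to a comparison table", {
  out <- generate_corpus(preset_config(n_docs = 150, seed = 28))
  fit <- fit_labeled_lda(out$corpus, iterations = 40, burn_in = 20, seed = 29)
  cmp <- mine_interests(out$corpus, fit, "acute_vs_chronic")
  expect_s3_class(cmp, "topic_comparison")
  expect_equal(nrow(cmp), 9)
  expect_setequal(cmp$label, load_taxonomy()$label_id)
  expect_equal(unique(cmp$group1), "acute")
  # thresholded ratios: every retained entry is 0 or > threshold floor
  ratios <- topic_ratios(fit$theta)
  expect_true(all(ratios == 0 | ratios >= 1 / 9))
})

test_that("p-value formatting truncates only below the cutoff", {
  expect_equal(format_p(c(0.0004, 0.034, NA)), c("<.001", ".034", NA))
})
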