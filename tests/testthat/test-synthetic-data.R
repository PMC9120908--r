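test_that("mixture fractions follow the cfDNA mixing identity", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(expected_mixture_fractions(tumor_model(w, f = 0)), w)
  # at f = 1 an arm at CN 4 doubles its weight before renormalization
  cn <- c(a = 4, b = 2, c = 2)
  p <- expected_mixture_fractions(tumor_model(w, cn, f = 1))
  expect_equal(unname(p), unname(c(2 * w["a"], w["b"], w["c"]) /
                                   (2 * w["a"] + w["b"] + w["c"])))
  set.seed(2)
  for (i in 1:10) {
    f <- runif(1)
    cn_r <- setNames(sample(0:4, 3, TRUE), names(w))
    expect_equal(sum(expected_mixture_fractions(tumor_model(w, cn_r, f))), 1)
  }
  expect_error(tumor_model(c(a = 0.5, b = 0.5), f = 1.2))
})

test_that("generators are pure functions of (parameters, seed)", {
  arms <- arm_table_hg19()
  w <- arm_weights(arms)
  expect_identical(simulate_panel(3, w, seed = 5)[[2]]$counts,
                   simulate_panel(3, w, seed = 5)[[2]]$counts)
  m <- tumor_model(w, uc_cn_profile(arms), f = 0.1)
  expect_identical(simulate_cfdna_sample(m, seed = 5)$counts,
                   simulate_cfdna_sample(m, seed = 5)$counts)
  expect_false(identical(simulate_cfdna_sample(m, seed = 5)$counts,
                         simulate_cfdna_sample(m, seed = 6)$counts))
  expect_identical(simulate_segments(m, arms, seed = 5),
                   simulate_segments(m, arms, seed = 5))
  expect_identical(simulate_variants(m, 4, seed = 5),
                   simulate_variants(m, 4, seed = 5))
  expect_identical(simulate_cohort(n = 30, seed = 5),
                   simulate_cohort(n = 30, seed = 5))
  # seeding does not clobber the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulate_cohort(n = 30, seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("pure multinomial sampling concentrates on the weights", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  v <- simulate_cfdna_sample(tumor_model(w, f = 0), total_reads = 1e6,
                             dispersion = Inf, seed = 10)
  fr <- v$counts / sum(v$counts)
  for (k in names(w))
    expect_lt(abs(fr[[k]] - w[[k]]), 3 * sqrt(w[[k]] * (1 - w[[k]]) / 1e6))
})

test_that("panel mean fractions sit within 3 SE of the generating weights", {
  arms <- arm_table_hg19()
  w <- arm_weights(arms)
  n <- 20; reads <- 1e5
  ctl <- simulate_panel(n, w, total_reads = reads, dispersion = Inf,
                        seed = 123)
  fr <- sapply(ctl, function(v) v$counts / sum(v$counts))
  mean_fr <- rowMeans(fr)
  se <- sqrt(w * (1 - w) / reads / n)     # multinomial SE oracle
  expect_true(all(abs(mean_fr - w) < 3.5 * se))
})

test_that("counts are non-negative and sum exactly to the requested depth", {
  arms <- arm_table_hg19()
  w <- arm_weights(arms)
  for (s in 1:5) {
    v <- simulate_cfdna_sample(tumor_model(w, uc_cn_profile(arms), f = 0.3),
                               total_reads = 54321, seed = s)
    expect_equal(sum(v$counts), 54321)
    expect_true(all(v$counts >= 0))
  }
  expect_error(simulate_cfdna_sample(tumor_model(w, f = 0), total_reads = 0),
               "total_reads")
})

test_that("noise-free segments recover the arm copy numbers exactly", {
  arms <- arm_table_hg19()
  m <- tumor_model(arm_weights(arms), uc_cn_profile(arms), f = 0.2)
  seg <- simulate_segments(m, arms, noise = 0, seed = 3)
  cn <- arm_copy_number(seg, arms)
  expect_equal(cn, m$cn[names(cn)])
  # with noise, recovery within 3 SDs of the weighted-mean noise
  seg2 <- simulate_segments(m, arms, noise = 0.1, seed = 4)
  cn2 <- arm_copy_number(seg2, arms)
  expect_true(all(abs(cn2 - m$cn[names(cn2)]) < 3 * 0.1))
})

test_that("plasma VAFs scale with tumor fraction", {
  arms <- arm_table_hg19()
  w <- arm_weights(arms)
  v0 <- simulate_variants(tumor_model(w, f = 0), n_variants = 10, seed = 1)
  expect_true(all(v0$plasma_vaf_num == 0))
  expect_true(all(v0$status %in% c("not_detected", "rejected")))
  v1 <- simulate_variants(tumor_model(w, f = 1), n_variants = 10,
                          tissue_vafs = rep(40, 10), mean_coverage = 5000,
                          seed = 2)
  expect_true(all(abs(v1$plasma_vaf_num - 40) < 5))
  expect_true(all(v1$status == "detected"))
})

test_that("max plasma VAF tracks the aneuploidy score across patients", {
  setup <- sim_setup(seed = 777)
  cn <- uc_cn_profile(setup$arms)
  set.seed(31)
  fs <- runif(30, 0, 0.3)
  res <- sapply(seq_along(fs), function(i) {
    m <- tumor_model(setup$w, cn, f = fs[i])
    v <- simulate_cfdna_sample(m, seed = 1000 + i)
    sc <- score_sample(v, setup$panel, setup$arms)$score
    calls <- simulate_variants(m, n_variants = 2, subject = as.character(i),
                               seed = 2000 + i)
    c(vaf = max(calls$plasma_vaf_num), score = sc)
  })
  expect_gt(spearman_cor(res["vaf", ], res["score", ])$rho, 0.6)
})

test_that("cohort generator recovers a null and a strong odds ratio", {
  coh_null <- simulate_cohort(n = 2000, or_score = 1, or_tfi = 1, seed = 9)
  est <- logistic_univariate(coh_null, "response", "score_high")$estimates
  expect_lt(abs(log(est$or[est$term == "score_high"])), 0.4)
  coh <- simulate_cohort(n = 74, seed = 10)
  expect_equal(nrow(coh), 74)
  expect_true(all(coh$time_on_treatment >= 21))
  expect_true(all(coh$time_on_treatment <= 735))
  expect_true(all(coh$event %in% 0:1))
  expect_error(simulate_cohort(n = 10), "n >= 20")
})

test_that("synthetic outputs feed every pipeline stage unchanged", {
  setup <- sim_setup(seed = 888)
  m <- tumor_model(setup$w, uc_cn_profile(setup$arms), f = 0.15)
  # counts -> scoring
  v <- simulate_cfdna_sample(m, seed = 1)
  res <- score_sample(v, setup$panel, setup$arms)
  expect_true(res$call %in% c("high", "low"))
  # segments -> concordance
  seg <- simulate_segments(m, setup$arms, seed = 2)
  d <- log2_deviation(arm_copy_number(seg, setup$arms))
  expect_silent(patient_concordance(d, res$z))
  # variants -> detection
  calls <- simulate_variants(m, 5, seed = 3)
  expect_s3_class(detection_rate(calls), "detection_summary")
  # cohort -> association
  coh <- simulate_cohort(n = 300, seed = 4)
  expect_s3_class(logistic_multivariate(coh, "response",
                                        c("score_high", "tfi_short"),
                                        cv = list(k = 5, repeats = 2),
                                        seed = 5), "logistic_result")
  expect_named(km_logrank(coh, "time_on_treatment", "event",
                          "score_high")$medians)
})
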