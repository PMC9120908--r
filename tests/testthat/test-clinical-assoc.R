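cohort_table <- function(a, b, c, d) {
  matrix(c(a, c, b, d), 2,
         dimnames = list(prediction = c("high", "low"),
                         outcome = c("non_responder", "responder")))
}

test_that("predictive metrics reproduce the published cohort 2x2", {
  # 21 score-high (2 with benefit), 53 score-low (24 with benefit)
  t <- cohort_table(19, 2, 29, 24)
  m <- predictive_metrics(t, "high", "non_responder")
  expect_equal(m$ppv, 19 / 21)          # 0.905, printed as 0.9
  expect_equal(m$sensitivity, 19 / 48)  # 40%
  expect_equal(m$specificity, 24 / 26)  # 92%
  expect_equal(m$npv, 24 / 53)
})

test_that("a perfect classifier scores 1 on all four metrics", {
  m <- predictive_metrics(cohort_table(10, 0, 0, 7), "high",
                          "non_responder")
  expect_equal(unlist(m[c("ppv", "npv", "sensitivity", "specificity")]),
               c(ppv = 1, npv = 1, sensitivity = 1, specificity = 1))
})

test_that("zero-margin metrics are NA with a warning, not errors", {
  expect_warning(m <- predictive_metrics(cohort_table(0, 0, 10, 10),
                                         "high", "non_responder"),
                 "PPV undefined")
  expect_true(is.na(m$ppv))
})

test_that("sensitivity equals PPV of the transposed, relabeled table", {
  set.seed(17)
  for (i in 1:25) {
    t <- matrix(rpois(4, 20) + 1, 2,
                dimnames = list(pred = c("pos", "neg"),
                                out = c("yes", "no")))
    m1 <- predictive_metrics(t, "pos", "yes")
    m2 <- predictive_metrics(t(t), "yes", "pos")
    expect_equal(m1$sensitivity, m2$ppv)
    expect_equal(m1$ppv, m2$sensitivity)
  }
})

test_that("chi-square matches the closed form sum((O-E)^2/E)", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square(flat, yates = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res2 <- chi_square(matrix(c(20, 10, 10, 20), 2), yates = FALSE)
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:100) {
    t <- matrix(rpois(4, 30) + 5, 2)
    expect_equal(chi_square(t, yates = FALSE)$statistic, oracle_chisq(t),
                 tolerance = 1e-12)
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("chi-square warns on small expected counts", {
  expect_warning(chi_square(matrix(c(2, 3, 3, 2), 2)), "below 5")
})

test_that("Kaplan-Meier medians follow the first-time-below-half rule", {
  df <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1,
                   group = rep(c("A", "B"), each = 3))
  km <- km_logrank(df, "time", "event", "group")
  expect_equal(unname(km$medians), c(2, 5))
  expect_gt(km$statistic, 0)
})

test_that("log-rank statistic is zero for identical groups", {
  df <- data.frame(time = rep(c(3, 8, 12, 20), 2),
                   event = rep(c(1, 0, 1, 1), 2),
                   group = rep(c("A", "B"), each = 4))
  km <- km_logrank(df, "time", "event", "group")
  expect_equal(km$statistic, 0, tolerance = 1e-12)
  expect_equal(km$p, 1, tolerance = 1e-12)
})

test_that("KM estimates equal a brute-force product-limit oracle", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    tt <- sample(30, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    df <- data.frame(time = c(tt, 100), event = c(ev, 1),
                     group = c(rep("A", n), "B"))
    km <- km_logrank(df, "time", "event", "group")
    got <- km$curves[km$curves$group == "A" & km$curves$n_event > 0, ]
    want <- oracle_km(tt, ev)
    expect_equal(got$surv, want$surv, tolerance = 1e-12)
  }
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(45)
  tt <- sample(50, 15, replace = TRUE)
  df <- data.frame(time = c(tt, 200), event = 1,
                   group = c(rep("A", 15), "B"))
  km <- km_logrank(df, "time", "event", "group")
  a <- km$curves[km$curves$group == "A", ]
  expect_equal(a$surv, sapply(a$time, function(t) mean(tt > t)))
})

test_that("a group that never reaches half survival has NA median", {
  df <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = c(1, 1, 1, 0, 0, 0),
                   group = rep(c("A", "B"), each = 3))
  expect_warning(km <- km_logrank(df, "time", "event", "group"), "B")
  expect_true(is.na(km$medians[["B"]]))
})

test_that("univariate logistic regression recovers a null covariate", {
  set.seed(50)
  df <- data.frame(y = rbinom(400, 1, 0.5), x = rbinom(400, 1, 0.5))
  fit <- logistic_univariate(df, "y", "x")
  est <- fit$estimates[fit$estimates$term == "x", ]
  expect_true(est$ci_low < 1 && est$ci_high > 1)
  expect_lt(abs(log(est$or)), 0.5)
  expect_error(logistic_univariate(data.frame(y = rep(1, 10), x = rnorm(10)),
                                   "y", "x"), "single class")
})

test_that("Wald intervals cover a true odds ratio at the nominal rate", {
  set.seed(51)
  hits <- replicate(200, {
    coh <- simulate_cohort(n = 500, or_score = 0.15, or_tfi = 1,
                           seed = sample.int(1e6, 1))
    est <- logistic_univariate(coh, "response", "score_high")$estimates
    est <- est[est$term == "score_high", ]
    est$ci_low <= 0.15 && 0.15 <= est$ci_high
  })
  expect_gte(mean(hits), 0.90)   # nominal 95%, binomial noise at 200 reps
})

test_that("separation is detected and the Firth fallback stays finite", {
  df <- data.frame(y = c(rep(0, 10), rep(1, 10)),
                   x = c(rnorm(10, -3), rnorm(10, 3)))
  expect_warning(logistic_univariate(df, "y", "x"), "separation")
  fit <- logistic_univariate(df, "y", "x", method = "firth")
  est <- fit$estimates[fit$estimates$term == "x", ]
  expect_true(is.finite(est$or) && est$or > 1)
  expect_true(is.finite(est$ci_high))
})

test_that("a single-covariate multivariate model equals the univariate fit", {
  coh <- simulate_cohort(n = 200, seed = 60)
  uni <- logistic_univariate(coh, "response", "score_high")
  multi <- logistic_multivariate(coh, "response", "score_high", cv = NULL)
  expect_equal(multi$estimates$or, uni$estimates$or)
  expect_equal(multi$estimates$p, uni$estimates$p)
})

test_that("two independent true effects are both recovered with sign", {
  set.seed(61)
  ok <- replicate(50, {
    coh <- simulate_cohort(n = 500, or_score = 0.2, or_tfi = 0.2,
                           seed = sample.int(1e6, 1))
    est <- logistic_multivariate(coh, "response",
                                 c("score_high", "tfi_short"),
                                 cv = NULL)$estimates
    all(est$or[est$term %in% c("score_high", "tfi_short")] < 1)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("covariate selection keeps univariately significant terms", {
  coh <- simulate_cohort(n = 500, or_score = 0.1, or_tfi = 1, seed = 62)
  coh$noise <- rnorm(nrow(coh))
  fit <- logistic_multivariate(coh, "response",
                               candidates = c("score_high", "noise"),
                               cv = NULL)
  expect_equal(fit$selected, "score_high")
})

test_that("repeated CV is bit-reproducible given (seed, k, repeats)", {
  coh <- simulate_cohort(n = 200, seed = 63)
  f1 <- logistic_multivariate(coh, "response", c("score_high", "tfi_short"),
                              cv = list(k = 10, repeats = 3), seed = 7)
  f2 <- logistic_multivariate(coh, "response", c("score_high", "tfi_short"),
                              cv = list(k = 10, repeats = 3), seed = 7)
  expect_identical(f1$cv$per_fold, f2$cv$per_fold)
  expect_equal(nrow(f1$cv$per_fold), 30)
  expect_true(f1$cv$mean_accuracy >= 0 && f1$cv$mean_accuracy <= 1)
  expect_true(f1$cv$mean_auc >= 0 && f1$cv$mean_auc <= 1)
  f3 <- logistic_multivariate(coh, "response", c("score_high", "tfi_short"),
                              cv = list(k = 10, repeats = 3), seed = 8)
  expect_false(identical(f1$cv$per_fold, f3$cv$per_fold))
  expect_error(logistic_multivariate(coh, "response", "score_high",
                                     cv = list(k = 10, repeats = 3)),
               "seed")
})

test_that("collinear designs fail loudly", {
  coh <- simulate_cohort(n = 100, seed = 64)
  coh$dup <- coh$score_high
  expect_error(logistic_multivariate(coh, "response", c("score_high", "dup"),
                                     cv = NULL), "singular|collinear")
})

test_that("VAF-score correlation ignores the square-root transform", {
  fx <- load_table1_fixture()
  mv <- max_vaf_per_patient(fx$variants)
  on_ <- vaf_score_correlation(mv, fx$scores, sqrt_transform = TRUE)
  off <- vaf_score_correlation(mv, fx$scores, sqrt_transform = FALSE)
  expect_equal(on_$rho, off$rho)
  expect_equal(on_$n, 17)
  # identity mapping gives rho 1
  s <- setNames(c(1, 4, 9, 16), letters[1:4])
  expect_equal(vaf_score_correlation(s, s)$rho, 1)
  expect_error(vaf_score_correlation(s[1:2], s[1:2]), "at least 3")
})
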