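#' 2x2 predictive metrics
#'
#' Sensitivity, specificity, PPV and NPV of a binary prediction for a
#' binary outcome. `t` is a 2x2 matrix with prediction in rows and outcome
#' in columns, both named. The metrics are computed for predicting
#' `positive_outcome` by `positive_prediction` (e.g. a high aneuploidy
#' score predicting non-response). Metrics with a zero denominator are
#' returned `NA` with a warning.
#'
#' @param t 2x2 integer matrix with dimnames (rows = prediction levels,
#'   columns = outcome levels).
#' @param positive_prediction row label treated as a positive prediction.
#' @param positive_outcome column label treated as the predicted outcome.
#' @return list with `ppv`, `npv`, `sensitivity`, `specificity` and the
#'   reordered table.
#' @export
predictive_metrics <- function(t, positive_prediction, positive_outcome) {
  stopifnot(is.matrix(t), all(dim(t) == 2), all(t >= 0),
            positive_prediction %in% rownames(t),
            positive_outcome %in% colnames(t))
  t <- t[c(positive_prediction, setdiff(rownames(t), positive_prediction)),
         c(positive_outcome, setdiff(colnames(t), positive_outcome))]
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator",
                            call. = FALSE); NA_real_ }
    else num / den
  }
  list(ppv = safe(a, a + b, "PPV"),
       npv = safe(d, c + d, "NPV"),
       sensitivity = safe(a, a + c, "sensitivity"),
       specificity = safe(d, b + d, "specificity"),
       table = t)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Wraps the standard Pearson chi-square test with optional Yates
#' continuity correction (on by default for 2x2 tables, mirroring common
#' statistical-package behavior); reports expected counts and warns when
#' any expected count is below 5.
#'
#' @param t contingency matrix.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square <- function(t, yates = TRUE) {
  stopifnot(is.matrix(t), all(t >= 0))
  if (sum(t) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero margin in contingency table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(t, correct = yates))
  if (any(res$expected < 5))
    warning("expected count below 5; chi-square approximation is weak",
            call. = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group with the median survival time
#' (first time at which the estimated survival drops to 0.5 or below) and
#' the two-sample log-rank test.
#'
#' @param data data frame.
#' @param time,event,group column names: positive times, 0/1 (or logical)
#'   event indicator, and a two-level grouping factor.
#' @return list with `curves` (data frame: group, time, n_risk, n_event,
#'   surv), `medians` (named, NA when the curve never reaches 0.5),
#'   `statistic`, `p`.
#' @export
km_logrank <- function(data, time, event, group) {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  gr <- factor(data[[group]])
  if (any(tt <= 0)) stop("non-positive survival times", call. = FALSE)
  if (nlevels(gr) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  fit <- survival::survfit(survival::Surv(tt, ev) ~ gr)
  sm <- summary(fit)
  strata <- sub("^gr=", "", as.character(sm$strata))
  curves <- data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv)
  medians <- vapply(levels(gr), function(g) {
    sub <- curves[curves$group == g, ]
    hit <- which(sub$surv <= 0.5)
    if (length(hit) == 0) NA_real_ else sub$time[min(hit)]
  }, numeric(1))
  if (anyNA(medians))
    warning("median survival undefined for group(s): ",
            paste(names(medians)[is.na(medians)], collapse = ", "),
            call. = FALSE)
  lr <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  list(curves = curves, medians = medians,
       statistic = lr$chisq, df = 1,
       p = stats::pchisq(lr$chisq, 1, lower.tail = FALSE))
}

# Mann-Whitney AUC of predicted probabilities against a 0/1 outcome.
auc_rank <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used as the separation fallback. Newton iterations on the modified score
# U*(b) = X'(y - p + h (1/2 - p)).
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * W
    I <- crossprod(X, XW)
    H <- X %*% solve(I, t(XW))        # hat matrix of the weighted LS
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  I <- crossprod(X, X * (p * (1 - p)))
  list(coefficients = drop(beta), vcov = solve(I), converged = it < max_iter)
}

# Shared fitting core: plain ML glm or Firth fallback, Wald OR/CI/p table,
# separation diagnostics.
fit_logistic <- function(data, outcome, covariates, method = c("ml", "firth")) {
  method <- match.arg(method)
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("outcome '", outcome, "' has a single class", call. = FALSE)
  stopifnot(all(y %in% c(0, 1)))
  fml <- stats::reformulate(covariates, response = "..y")
  df <- data[, covariates, drop = FALSE]
  df$..y <- y
  mm <- stats::model.matrix(fml, df)
  if (qr(mm)$rank < ncol(mm))
    stop("singular design matrix; collinear covariate(s) among: ",
         paste(covariates, collapse = ", "), call. = FALSE)
  separated <- FALSE
  if (method == "firth") {
    ft <- firth_logistic(mm, y)
    coef <- ft$coefficients
    se <- sqrt(diag(ft$vcov))
    fitted <- stats::plogis(drop(mm %*% coef))
    fit <- ft
  } else {
    fit <- withCallingHandlers(
      stats::glm(fml, data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    coef <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    fitted <- stats::fitted(fit)
    if (separated || any(abs(coef[-1]) > 15))
      warning("possible complete/quasi-complete separation; Wald estimates ",
              "are unreliable (consider method = \"firth\")", call. = FALSE)
  }
  est <- data.frame(term = names(coef) %||% colnames(mm),
                    or = exp(coef),
                    ci_low = exp(coef - stats::qnorm(0.975) * se),
                    ci_high = exp(coef + stats::qnorm(0.975) * se),
                    p = 2 * stats::pnorm(-abs(coef / se)),
                    row.names = NULL)
  list(estimates = est, fit = fit, y = y, model_matrix = mm,
       fitted = fitted, method = method, separated = separated,
       outcome = outcome, covariates = covariates)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood fit of a binary outcome on a single covariate, with
#' odds ratio, Wald 95\% confidence interval and Wald p-value. Complete or
#' quasi-complete separation is detected and flagged with a warning rather
#' than silently reported; a Firth-penalized fit is available via
#' `method = "firth"`.
#'
#' @param data data frame.
#' @param outcome name of a 0/1 (or two-level factor/logical) column.
#' @param covariate single covariate name.
#' @param method "ml" (default) or "firth".
#' @return A `logistic_result` with an `estimates` table.
#' @export
logistic_univariate <- function(data, outcome, covariate,
                                method = c("ml", "firth")) {
  stopifnot(length(covariate) == 1)
  res <- fit_logistic(data, outcome, covariate, method)
  structure(res, class = "logistic_result")
}

#' Multivariate logistic regression with repeated cross-validation
#'
#' Joint maximum-likelihood fit of a binary outcome on several covariates,
#' followed by repeated stratified k-fold cross-validation (default 10-fold,
#' 3 repeats) reporting per-fold and mean accuracy and AUC. When
#' `covariates` is NULL they are selected as the candidates with univariate
#' Wald p < 0.05. Fold assignment is a deterministic function of `seed`.
#'
#' @inheritParams logistic_univariate
#' @param covariates covariate names, or NULL to select from `candidates`.
#' @param candidates candidate covariates for univariate selection.
#' @param cv list with `k` and `repeats`.
#' @param seed integer seed controlling fold assignment (required for CV).
#' @return A `logistic_result` with `estimates`, `cv` (per-fold and mean
#'   accuracy/AUC) and `selected` covariates.
#' @export
logistic_multivariate <- function(data, outcome, covariates = NULL,
                                  candidates = NULL,
                                  cv = list(k = 10, repeats = 3),
                                  seed = NULL, method = c("ml", "firth")) {
  method <- match.arg(method)
  if (is.null(covariates)) {
    if (is.null(candidates))
      stop("give either covariates or candidates", call. = FALSE)
    pvals <- vapply(candidates, function(v)
      logistic_univariate(data, outcome, v, method)$estimates$p[2],
      numeric(1))
    covariates <- candidates[pvals < 0.05]
    if (length(covariates) == 0)
      stop("no candidate reached univariate p < 0.05", call. = FALSE)
  }
  if (nrow(data) < 10 * length(covariates))
    warning("fewer than 10 observations per covariate", call. = FALSE)
  res <- fit_logistic(data, outcome, covariates, method)
  res$selected <- covariates
  if (!is.null(cv)) {
    if (is.null(seed)) stop("cross-validation requires a seed", call. = FALSE)
    res$cv <- cv_logistic(data, outcome, covariates, k = cv$k,
                          repeats = cv$repeats, seed = seed, method = method)
  }
  structure(res, class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat("<logistic_result>", x$method, "fit of", x$outcome, "on",
      paste(x$covariates, collapse = " + "), "\n")
  print(transform(x$estimates, or = round(or, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3), p = signif(p, 3)))
  if (!is.null(x$cv))
    cat(sprintf("CV (%d-fold x %d): accuracy %.3f, AUC %.3f\n",
                x$cv$k, x$cv$repeats, x$cv$mean_accuracy, x$cv$mean_auc))
  invisible(x)
}

# Stratified fold labels: within each outcome class, a seeded shuffle is
# dealt round-robin over folds, so fold sizes and class balance are as even
# as possible and the assignment is bit-reproducible.
stratified_folds <- function(y, k, repeats, seed) {
  with_seed(seed, lapply(seq_len(repeats), function(r) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
    fold
  }))
}

cv_logistic <- function(data, outcome, covariates, k, repeats, seed,
                        method = "ml") {
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  folds <- stratified_folds(y, k, repeats, seed)
  per_fold <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    do.call(rbind, lapply(seq_len(k), function(f) {
      test <- folds[[r]] == f
      if (!any(test) || length(unique(y[!test])) < 2)
        return(NULL)
      fit <- suppressWarnings(
        fit_logistic(data[!test, , drop = FALSE], outcome, covariates,
                     method))
      mm <- stats::model.matrix(stats::reformulate(covariates),
                                data[test, , drop = FALSE])
      b <- if (method == "firth") fit$fit$coefficients
           else stats::coef(fit$fit)
      prob <- stats::plogis(drop(mm %*% b))
      data.frame(repeat_ = r, fold = f,
                 accuracy = mean((prob >= 0.5) == (y[test] == 1)),
                 auc = auc_rank(prob, y[test]))
    }))
  }))
  list(k = k, repeats = repeats, seed = seed, per_fold = per_fold,
       mean_accuracy = mean(per_fold$accuracy),
       mean_auc = mean(per_fold$auc, na.rm = TRUE))
}

#' Correlation between maximal plasma VAF and aneuploidy score
#'
#' Spearman correlation over subjects with both a defined maximal plasma
#' VAF and an aneuploidy score. A square-root transform (used for plotting
#' to reduce skewness) can be applied; being strictly monotone it provably
#' leaves rho unchanged.
#'
#' @param max_vafs named vector of per-subject maximal plasma VAFs
#'   (NA = undefined).
#' @param scores named vector of per-subject aneuploidy scores.
#' @param sqrt_transform apply sqrt to both axes before correlating.
#' @return list with `rho`, `p`, `n`.
#' @export
vaf_score_correlation <- function(max_vafs, scores, sqrt_transform = TRUE) {
  shared <- intersect(names(max_vafs)[!is.na(max_vafs)],
                      names(scores)[!is.na(scores)])
  if (length(shared) < 3)
    stop("need at least 3 subjects with VAF and score", call. = FALSE)
  x <- max_vafs[shared]; y <- scores[shared]
  if (sqrt_transform) { x <- sqrt(x); y <- sqrt(y) }
  spearman_cor(x, y)
}
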