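# simulated experiment covariates resembling the study's ranges
make_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(e_type = rbinom(n, 1, 0.5),
             e_num = sample(1:8, n, replace = TRUE),
             hg = runif(n, 1, 6),
             beta = runif(n, 1, 15),
             recall_p = runif(n, 0.05, 0.5),
             trials = sample(100:400, n, replace = TRUE))
}

test_that("experiment summaries assemble and validate the covariates", {
  s <- summarize_experiment(e_type = 1, e_num = 3, snr_hg = c(2, 4),
                            snr_beta = c(1, 3), recall_p = 0.25,
                            trials = 144, auroc = 0.61)
  expect_equal(s$e_num, 3)
  expect_equal(s$hg, 3)   # mean of per-channel SNRs
  expect_equal(s$beta, 2)
  expect_error(summarize_experiment(1, 3, NA, 2, .2, 100, .5), "NA")
  expect_error(summarize_experiment(2, 3, 1, 2, .2, 100, .5))
})

test_that("the default design has the 41 curated interaction terms", {
  terms <- glm_terms_default()
  expect_length(terms, 41)
  expect_true("e_num:hg:beta:recall_p" %in% terms)
  expect_true("e_type:e_num:hg:beta:recall_p:trials" %in% terms)
})

test_that("a noiseless linear response is recovered exactly", {
  d <- make_covariates(62, seed = 1)
  d$auroc <- 0.4 + 0.01 * d$e_num
  fit <- fit_auroc_glm(d)
  co <- fit$coefficients
  expect_equal(co$Estimate[co$Name == "(Intercept)"], 0.4, tolerance = 1e-6)
  expect_equal(co$Estimate[co$Name == "e_num"], 0.01, tolerance = 1e-6)
  others <- co$Estimate[!co$Name %in% c("(Intercept)", "e_num")]
  expect_lt(max(abs(others)), 1e-6)
  expect_equal(fit$df2, 62 - 42)  # residual d.f. 20 at n = 62
})

test_that("fit is the closed-form least-squares solution", {
  d <- make_covariates(62, seed = 2)
  set.seed(3)
  d$auroc <- 0.5 + 0.02 * d$hg - 0.01 * d$beta + rnorm(62, 0, 0.05)
  fit <- fit_auroc_glm(d)
  X <- stats::model.matrix(stats::formula(fit$fit), data = d)
  beta_hat <- solve(crossprod(X), crossprod(X, d$auroc))
  expect_equal(unname(fit$coefficients$Estimate), as.numeric(beta_hat),
               tolerance = 1e-8)
})

test_that("coefficients are invariant to the row order of experiments", {
  d <- make_covariates(62, seed = 4)
  set.seed(5)
  d$auroc <- 0.5 + 0.01 * d$e_num + rnorm(62, 0, 0.03)
  f1 <- fit_auroc_glm(d)
  f2 <- fit_auroc_glm(d[sample(62), ])
  expect_equal(f1$coefficients$Estimate, f2$coefficients$Estimate,
               tolerance = 1e-9)
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
})

test_that("centering covariates changes terms but not fitted values", {
  # fitted-value invariance under centering requires a hierarchically
  # closed design, i.e. the full factorial (the curated term set is not
  # closed under the reparameterization)
  d <- make_covariates(90, seed = 6)
  set.seed(7)
  d$auroc <- 0.5 + 0.005 * d$e_num + rnorm(90, 0, 0.02)
  f1 <- fit_auroc_glm(d, full_factorial = TRUE)
  dc <- d
  for (v in c("hg", "beta", "recall_p", "trials"))
    dc[[v]] <- dc[[v]] - mean(dc[[v]])
  f2 <- fit_auroc_glm(dc, full_factorial = TRUE)
  expect_equal(unname(predict(f1$fit)), unname(predict(f2$fit)),
               tolerance = 1e-6)
})

test_that("rank-deficient designs fail with a naming error", {
  d <- make_covariates(62, seed = 8)
  d$beta <- 2 * d$hg  # collinear
  d$auroc <- runif(62, 0.4, 0.7)
  expect_error(fit_auroc_glm(d), "collinear|deficient")
})

test_that("confidence intervals cover planted coefficients at 95%", {
  # planted main effects + noise; nominal t-based coverage pooled over
  # terms and replicates
  truth <- c("(Intercept)" = 0.45, e_num = 0.008, hg = 0.01)
  reps <- 400
  covered <- total <- 0
  set.seed(10)
  for (r in seq_len(reps)) {
    d <- make_covariates(62)
    d$auroc <- 0.45 + 0.008 * d$e_num + 0.01 * d$hg + rnorm(62, 0, 0.04)
    fit <- fit_auroc_glm(d)
    co <- fit$coefficients
    tcrit <- stats::qt(0.975, fit$df2)
    full_truth <- setNames(rep(0, nrow(co)), co$Name)
    full_truth[names(truth)] <- truth
    lo <- co$Estimate - tcrit * co$SE
    hi <- co$Estimate + tcrit * co$SE
    covered <- covered + sum(lo <= full_truth & full_truth <= hi)
    total <- total + nrow(co)
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.98)
})

test_that("whole-model p-values are uniform under a pure-noise response", {
  set.seed(11)
  p <- replicate(400, {
    d <- make_covariates(62)
    d$auroc <- 0.55 + rnorm(62, 0, 0.05)
    fit_auroc_glm(d)$p_model
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
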