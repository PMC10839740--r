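# The hierarchical Bayesian regression fit: covariate transform, oracles
# (closed-form conjugate posterior, generator-truth recovery, JAGS
# cross-check), prediction, shrinkage and input validation.

test_that("age standardization is exact and invertible", {
  tr <- age_transform(center = 50, scale = 25)
  expect_equal(standardize_age(50, tr), 0)
  expect_equal(standardize_age(75, tr), 1.0)
  set.seed(1)
  ages <- stats::runif(100, 0, 100)
  expect_lt(max(abs(unstandardize_age(standardize_age(ages, tr), tr) - ages)),
            1e-12)
  expect_error(age_transform(center = 1, scale = 0), "scale")
  expect_error(age_transform(ages = rep(5, 3)), "scale")  # zero-sd ages
})

test_that("single-batch posterior matches the closed-form conjugate oracle", {
  set.seed(42)
  n <- 2000
  age <- stats::runif(n, 20, 80)
  y <- 3.0 - 0.012 * age + stats::rnorm(n, 0, 0.2)
  cohort <- data.frame(subject_id = as.character(seq_len(n)), site = "s1",
                       sex = "F", age = age, roi_a = y)
  # pin the between-batch SDs near zero: the batch line equals the global line
  priors <- prior_spec(
    mu_alpha = list(dist = "normal", location = 0, scale = 5),
    tau_alpha = list(dist = "halfnormal", scale = 1e-8),
    mu_beta = list(dist = "normal", location = 0, scale = 5),
    tau_beta = list(dist = "halfnormal", scale = 1e-8),
    mu_logsigma = list(dist = "normal", location = 0, scale = 2),
    tau_logsigma = list(dist = "halfnormal", scale = 1e-8)
  )
  fit <- hbr_fit(cohort, priors = priors,
                 control = hbr_control(chains = 2, warmup = 500, iter = 500,
                                       seed = 2))
  reg <- fit$rois$a$batch

  # oracle: Bayesian linear regression with N(0, 5^2) coefficient priors and
  # the noise variance fixed at its sample estimate
  x <- standardize_age(age, fit$transform)
  X <- cbind(1, x)
  s2 <- summary(stats::lm(y ~ x))$sigma^2
  P <- crossprod(X) / s2 + diag(1 / 25, 2)
  m <- solve(P, crossprod(X, y) / s2)
  expect_lt(abs(reg$alpha_mean - m[1]), 3 * sqrt(reg$alpha_var))
  expect_lt(abs(reg$beta_mean - m[2]), 3 * sqrt(reg$beta_var))
  # and the posterior SDs agree with the oracle's to Monte-Carlo accuracy
  V <- solve(P)
  expect_equal(sqrt(reg$alpha_var), sqrt(V[1, 1]), tolerance = 0.25)
  expect_equal(sqrt(reg$beta_var), sqrt(V[2, 2]), tolerance = 0.25)
})

test_that("hyperparameter posteriors recover the generator truth", {
  fx <- small_ref()
  ih <- implied_hyperparameters(fx$truth, fx$fit$transform)
  hs <- hyperposterior_summary(fx$fit)
  m <- merge(hs, ih, by = c("roi", "hyper"))
  expect_equal(nrow(m), 12L)
  expect_true(all(abs(m$mean - m$value) <= 3 * m$sd))
})

test_that("refitting with identical seed and settings reproduces draws exactly", {
  fx <- small_ref()
  fit2 <- suppressWarnings(
    hbr_fit(fx$cohort, control = quick_control(5, chains = 2)))
  expect_identical(fx$fit$rois$r01$draws, fit2$rois$r01$draws)
  expect_identical(coef(fx$fit), coef(fit2))
  fit3 <- suppressWarnings(
    hbr_fit(fx$cohort, rois = "r01", control = quick_control(6)))
  expect_false(identical(fx$fit$rois$r01$draws, fit3$rois$r01$draws))
})

test_that("degenerate posteriors predict the exact batch line and noise SD", {
  fx <- small_target()
  mod <- model_from_truth(fx$truth)
  bp <- fx$truth$batch_params
  p1 <- bp[bp$batch == "w1:F" & bp$roi == "r01", ]
  nd <- data.frame(wave = "w1", sex = "F", age = c(7, 9.5))
  pr <- predict(mod, nd, rois = "r01")
  expect_equal(unname(pr$mean[, "r01"]), p1$alpha + p1$beta * c(7, 9.5))
  expect_equal(unname(pr$sd[, "r01"]),
               rep(sqrt(p1$sigma^2 + fx$truth$omega^2), 2))
})

test_that("full predictive SD dominates the noise-only SD everywhere", {
  fx <- small_ref()
  nd <- fx$cohort[sample.int(nrow(fx$cohort), 200), ]
  full <- predict(fx$fit, nd, sd_mode = "full")
  noise <- predict(fx$fit, nd, sd_mode = "noise_only")
  expect_true(all(full$sd >= noise$sd))
})

test_that("predictive SD is minimal at the posterior pivot age", {
  # registry with known (alpha, beta) covariance: Var(a + b x) is a parabola
  # minimized at x* = -cov/var_b
  fx <- small_target()
  mod <- model_from_truth(fx$truth)
  reg <- mod$rois$r01$batch
  i <- which(reg$batch == "w1:F")
  mod$rois$r01$batch$alpha_var[i] <- 0.04
  mod$rois$r01$batch$beta_var[i] <- 0.01
  mod$rois$r01$batch$alphabeta_cov[i] <- 0.008
  ages <- seq(-5, 5, by = 0.1)  # transform is identity, so x = age
  pr <- predict(mod, data.frame(wave = "w1", sex = "F", age = ages),
                rois = "r01")
  expect_equal(ages[which.min(pr$sd[, "r01"])], -0.008 / 0.01)
})

test_that("unknown batches are refused with a pointer to adaptation", {
  fx <- small_ref()
  nd <- data.frame(site = "siteXX", sex = "F", age = 30)
  expect_error(predict(fx$fit, nd), "siteXX:F")
  expect_error(predict(fx$fit, nd), "adapt")
})

test_that("batch posterior means shrink from the batch OLS toward the pooled mean", {
  # one severely under-sampled batch among well-sampled ones
  set.seed(31)
  alphas <- c(2.4, 2.6, 2.8, 3.0, 3.2, 2.1)
  ns <- c(rep(300, 5), 8)
  rows <- list()
  for (b in seq_along(alphas)) {
    age <- stats::runif(ns[b], 20, 80)
    rows[[b]] <- data.frame(
      subject_id = sprintf("s%d_%d", b, seq_len(ns[b])),
      site = sprintf("site%d", b), sex = "F", age = age,
      roi_a = alphas[b] - 0.01 * age + stats::rnorm(ns[b], 0, 0.2))
  }
  co <- do.call(rbind, rows)
  fit <- suppressWarnings(
    hbr_fit(co, control = hbr_control(chains = 2, warmup = 500, iter = 500,
                                      seed = 3)))
  x <- standardize_age(co$age, fit$transform)
  small_idx <- co$site == "site6"
  ols <- unname(stats::coef(stats::lm(co$roi_a[small_idx] ~ x[small_idx]))[1])
  post <- fit$rois$a$batch$alpha_mean[fit$rois$a$batch$batch == "site6:F"]
  mu <- hyperposterior_summary(fit)
  mu_a <- mu$mean[mu$hyper == "mu_alpha"]
  # posterior mean lies strictly between the batch OLS and the pooled mean
  expect_true((post - ols) * (mu_a - ols) > 0)
  expect_lt(abs(post - mu_a), abs(ols - mu_a))
})

test_that("undersized batches and incomplete thickness are rejected", {
  fx <- small_ref()
  co <- fx$cohort
  co$site[1:2] <- "tiny"
  expect_error(hbr_fit(co, control = quick_control(1)), "fewer than 3")
  co2 <- fx$cohort
  co2$roi_r01[5] <- NA
  expect_error(hbr_fit(co2, control = quick_control(1)), "roi_r01")
})

test_that("hyperposterior summaries equal draw moments and floor degenerate SDs", {
  fx <- small_ref()
  d <- fx$fit$rois$r01$draws
  hy <- d[, c("mu_alpha", "tau_alpha", "mu_beta", "tau_beta",
              "mu_logsigma", "tau_logsigma")]
  hs <- hyperposterior_summary(fx$fit)
  hs1 <- hs[hs$roi == "r01", ]
  expect_equal(hs1$mean[match(colnames(hy), hs1$hyper)],
               unname(colMeans(hy)), tolerance = 1e-12)
  # degenerate draw sets cannot produce zero-width transfer priors
  broken <- fx$fit
  broken$rois$r01$hyper$sd <- 0
  hs2 <- hyperposterior_summary(broken)
  expect_true(all(hs2$sd[hs2$roi == "r01"] > 0))
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  set.seed(21)
  B <- 8; nb <- 40
  alphas <- stats::rnorm(B, 2.8, 0.1)
  betas <- stats::rnorm(B, -0.25, 0.05)
  x <- stats::runif(B * nb, -2, 2)
  bidx <- rep(seq_len(B), each = nb)
  y <- alphas[bidx] + betas[bidx] * x + stats::rnorm(B * nb, 0, 0.2)
  co <- data.frame(subject_id = as.character(seq_along(x)),
                   site = sprintf("s%d", bidx), sex = "F",
                   age = x, roi_a = y)
  fit <- suppressWarnings(hbr_fit(
    co, transform = age_transform(center = 0, scale = 1),
    control = hbr_control(chains = 2, warmup = 1000, iter = 1000, seed = 4)))
  pr <- default_priors(y)

  jm <- "model {
    for (i in 1:N) {
      y[i] ~ dnorm(alpha[b[i]] + beta[b[i]] * x[i], pow(sigma[b[i]], -2))
    }
    for (j in 1:B) {
      alpha[j] ~ dnorm(mu_a, pow(tau_a, -2))
      beta[j] ~ dnorm(mu_b, pow(tau_b, -2))
      ls[j] ~ dnorm(mu_l, pow(tau_l, -2))
      sigma[j] <- exp(ls[j])
    }
    mu_a ~ dnorm(pm_a, pow(ps_a, -2))
    mu_b ~ dnorm(0, pow(ps_b, -2))
    mu_l ~ dnorm(pm_l, pow(2, -2))
    tau_a ~ dnorm(0, pow(ts_a, -2)) T(0,)
    tau_b ~ dnorm(0, pow(ts_b, -2)) T(0,)
    tau_l ~ dnorm(0, 1) T(0,)
  }"
  jd <- list(y = y, x = x, b = bidx, N = length(y), B = B,
             pm_a = pr$mu_alpha$location, ps_a = pr$mu_alpha$scale,
             ps_b = pr$mu_beta$scale, pm_l = pr$mu_logsigma$location,
             ts_a = pr$tau_alpha$scale, ts_b = pr$tau_beta$scale)
  jmod <- rjags::jags.model(textConnection(jm), data = jd, n.chains = 2,
                            quiet = TRUE,
                            inits = list(.RNG.name = "base::Mersenne-Twister",
                                         .RNG.seed = 99))
  stats::update(jmod, 1000, progress.bar = "none")
  js <- rjags::coda.samples(jmod, c("mu_a", "mu_b", "alpha", "sigma"),
                            n.iter = 2000, progress.bar = "none")
  jdraws <- do.call(rbind, lapply(js, as.matrix))

  hs <- hyperposterior_summary(fit)
  g <- function(h) hs$mean[hs$roi == "a" & hs$hyper == h]
  # hyper means agree within combined Monte-Carlo uncertainty
  expect_equal(g("mu_alpha"), mean(jdraws[, "mu_a"]), tolerance = 0.02)
  expect_equal(g("mu_beta"), mean(jdraws[, "mu_b"]), tolerance = 0.02)
  reg <- fit$rois$a$batch
  for (j in c(1L, 4L, 8L)) {
    expect_equal(reg$alpha_mean[reg$batch == sprintf("s%d:F", j)],
                 mean(jdraws[, sprintf("alpha[%d]", j)]), tolerance = 0.02)
    expect_equal(reg$sigma_mean[reg$batch == sprintf("s%d:F", j)],
                 mean(jdraws[, sprintf("sigma[%d]", j)]), tolerance = 0.02)
  }
})

test_that("deviation scores are invariant to the measurement unit", {
  fx <- small_ref()
  co_mm <- fx$cohort
  co_um <- co_mm
  co_um$roi_r01 <- co_um$roi_r01 * 1000
  co_um$roi_r02 <- co_um$roi_r02 * 1000
  fit_mm <- suppressWarnings(hbr_fit(co_mm, control = quick_control(9)))
  fit_um <- suppressWarnings(hbr_fit(co_um, control = quick_control(9)))
  z_mm <- residuals(fit_mm, co_mm)
  z_um <- residuals(fit_um, co_um)
  expect_lt(max(abs(z_mm - z_um)), 1e-6)
})

test_that("simulate() draws match the predictive moments", {
  fx <- small_target()
  mod <- model_from_truth(fx$truth)
  nd <- data.frame(wave = "w2", sex = "M", age = rep(10, 4000))
  sims <- simulate(mod, nsim = 1, seed = 2, newdata = nd)[[1]]
  pr <- predict(mod, nd[1, , drop = FALSE])
  m <- unname(pr$mean[1, "r01"]); s <- unname(pr$sd[1, "r01"])
  expect_lt(abs(mean(sims[, "r01"]) - m), 4 * s / sqrt(4000))
  expect_equal(stats::sd(sims[, "r01"]), s, tolerance = 0.05)
})
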