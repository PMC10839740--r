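# Transfer of the reference hyperposterior: informed priors, adaptation-set
# sampling with validation withholding, and adaptation to unseen batches.

test_that("transfer priors pass the hyperposterior through as Normal priors", {
  fx <- small_ref()
  hs <- hyperposterior_summary(fx$fit)
  tp <- transfer_priors(hs)
  expect_setequal(names(tp), fx$fit$roi_names)
  h1 <- hs[hs$roi == "r01", ]
  g <- function(nm, what) h1[[what]][h1$hyper == nm]
  expect_equal(tp$r01$mu_beta$location, g("mu_beta", "mean"))
  expect_equal(tp$r01$mu_beta$scale, g("mu_beta", "sd"))
  expect_equal(tp$r01$mu_beta$dist, "normal")
  # tau priors are zero-truncated regardless of the summary
  for (nm in c("tau_alpha", "tau_beta", "tau_logsigma")) {
    expect_equal(tp$r01[[nm]]$dist, "truncnormal")
    expect_equal(tp$r01[[nm]]$location, g(nm, "mean"))
  }
  # building twice from the same summary is identical
  expect_identical(tp, transfer_priors(hs))
  # missing hyperparameter refused
  expect_error(transfer_priors(hs[hs$hyper != "tau_beta", ]), "tau_beta")
})

test_that("adaptation sets withhold validation scans and partition the cohort", {
  sim <- small_target()
  co <- sim$cohort
  ad <- sample_adaptation_set(co, 50, strategy = "random", seed = 3)

  # exactly n per wave-by-sex batch
  key <- paste(ad$data$wave, ad$data$sex, sep = ":")
  expect_true(all(table(key) == 50))

  # partition: adaptation + remainder + withheld = cohort (clinical scans
  # are not in the adaptation set but stay in the remainder)
  expect_length(intersect(ad$data$row_id, ad$remainder$row_id), 0)
  expect_length(intersect(ad$data$row_id, ad$withheld$row_id), 0)
  expect_setequal(c(ad$data$row_id, ad$remainder$row_id, ad$withheld$row_id),
                  co$row_id)

  # subjects with all three waves and overlap-window wave-1 scans withheld
  nw <- tapply(co$wave, co$subject_id, function(w) length(unique(w)))
  long_ids <- names(nw)[nw == 3]
  expect_length(intersect(ad$data$subject_id, long_ids), 0)
  ow <- ad$overlap_window
  w1_overlap <- co$row_id[co$wave == "w1" & co$age >= ow[1] & co$age <= ow[2]]
  expect_length(intersect(ad$data$row_id, w1_overlap), 0)
  expect_true(all(w1_overlap %in% ad$withheld$row_id))

  # preterm scans never adapt
  expect_true(all(ad$data$group == "control"))

  # determinism and seed sensitivity
  ad2 <- sample_adaptation_set(co, 50, strategy = "random", seed = 3)
  expect_identical(ad$data$row_id, ad2$data$row_id)
  ad3 <- sample_adaptation_set(co, 50, strategy = "random", seed = 4)
  expect_false(identical(ad$data$row_id, ad3$data$row_id))

  # oversized requests fail with a sized message
  expect_error(sample_adaptation_set(co, 10000, seed = 1), "10000")
})

test_that("age-uniform sampling covers a peaked age distribution more evenly", {
  sim <- small_target()
  co <- sim$cohort
  sds <- vapply(1:50, function(s) {
    au <- sample_adaptation_set(co, 20, strategy = "age_uniform", seed = s)
    rn <- sample_adaptation_set(co, 20, strategy = "random", seed = s)
    w2 <- function(a) a$data$age[a$data$wave == "w2"]
    c(stats::sd(w2(au)), stats::sd(w2(rn)))
  }, c(0, 0))
  # wave 2 ages are triangular-peaked; uniform-bin sampling spreads them
  expect_gte(stats::median(sds[1, ] - sds[2, ]), 0)
  expect_gt(mean(sds[1, ] > sds[2, ]), 0.5)
})

test_that("adaptation refuses batches already known to the reference model", {
  fx <- small_ref()
  expect_error(
    hbr_adapt(fx$fit, fx$cohort, batch_vars = c("site", "sex"),
              control = quick_control(1)),
    "already present")
})

test_that("prior-only adaptation reverts to the hyperprior means", {
  fx <- small_ref()
  empty <- fx$cohort[0, ]
  expect_error(hbr_adapt(fx$fit, empty, control = quick_control(1)),
               "prior_only")
  mod <- suppressWarnings(
    hbr_adapt(fx$fit, empty, batch_vars = c("wave", "sex"),
              control = hbr_control(chains = 2, warmup = 300, iter = 600,
                                    seed = 7),
              prior_only = TRUE, new_batches = c("wZ:F", "wZ:M")))
  hs <- hyperposterior_summary(fx$fit)
  mu_a <- hs$mean[hs$roi == "r01" & hs$hyper == "mu_alpha"]
  tau_a <- hs$mean[hs$roi == "r01" & hs$hyper == "tau_alpha"]
  reg <- mod$rois$r01$batch
  a_new <- reg$alpha_mean[reg$batch == "wZ:F"]
  # with no data the posterior is the (informed) prior: the batch intercept
  # centers on the reference mu_alpha, within Monte-Carlo error of draws
  # spread by roughly tau_alpha
  expect_lt(abs(a_new - mu_a), 5 * tau_a / sqrt(200))
  expect_true(reg$transferred[reg$batch == "wZ:F"])
})

two_wave_target <- function() fixture("two_wave_target", function() {
  cfg2 <- cohort_config(
    n_rois = 2, n_sites_ref = 6, subjects_per_site_ref = 60,
    target_waves = data.frame(
      wave = c("w1", "w2"), scanner = c("sA", "sB"),
      lo = c(6, 8.6), hi = c(10.7, 12), n = c(1200L, 1200L),
      age_dist = "uniform", stringsAsFactors = FALSE),
    longitudinal_fraction = 0, preterm_fraction = 0)
  simulate_target_cohort(cfg2, seed = 21)
})

test_that("large adaptation sets converge to the per-batch least-squares fit", {
  fx <- small_ref()
  tgt <- two_wave_target()
  ad <- sample_adaptation_set(tgt$cohort, 450, seed = 22,
                              overlap_window = NULL)
  mod <- suppressWarnings(
    hbr_adapt(fx$fit, ad, control = hbr_control(chains = 2, warmup = 400,
                                                iter = 400, seed = 23)))
  x <- standardize_age(ad$data$age, fx$fit$transform)
  key <- paste(ad$data$wave, ad$data$sex, sep = ":")
  for (b in unique(key)) {
    i <- key == b
    ols <- unname(stats::coef(stats::lm(ad$data$roi_r01[i] ~ x[i])))
    reg <- mod$rois$r01$batch
    j <- reg$batch == b
    expect_lt(abs(reg$alpha_mean[j] - ols[1]), 3 * sqrt(reg$alpha_var[j]))
    expect_lt(abs(reg$beta_mean[j] - ols[2]), 3 * sqrt(reg$beta_var[j]))
  }
})

test_that("adapted batch estimates approach the MLE as the set grows", {
  fx <- small_ref()
  tgt <- two_wave_target()
  err <- vapply(c(25, 100, 400), function(n) {
    ad <- sample_adaptation_set(tgt$cohort, n, seed = 30,
                                overlap_window = NULL)
    mod <- suppressWarnings(
      hbr_adapt(fx$fit, ad, control = quick_control(30 + n)))
    x <- standardize_age(ad$data$age, fx$fit$transform)
    key <- paste(ad$data$wave, ad$data$sex, sep = ":")
    d <- c()
    for (r in c("r01", "r02")) {
      for (b in unique(key)) {
        i <- key == b
        ols <- unname(stats::coef(
          stats::lm(ad$data[[paste0("roi_", r)]][i] ~ x[i])))[1]
        reg <- mod$rois[[r]]$batch
        d <- c(d, abs(reg$alpha_mean[reg$batch == b] - ols))
      }
    }
    stats::median(d)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("adaptation leaves the serialized reference model untouched", {
  fx <- small_ref()
  tgt <- small_target()
  f1 <- tempfile(fileext = ".json")
  save_model(fx$fit, f1)
  before <- tools::md5sum(f1)
  ad <- sample_adaptation_set(tgt$cohort, 30, seed = 8)
  mod <- suppressWarnings(hbr_adapt(fx$fit, ad, control = quick_control(8)))
  f2 <- tempfile(fileext = ".json")
  save_model(fx$fit, f2)
  expect_identical(unname(before), unname(tools::md5sum(f2)))
  # reference batches inside the adapted model equal the reference registry
  ref_reg <- fx$fit$rois$r01$batch
  ad_reg <- mod$rois$r01$batch
  carried <- ad_reg[!ad_reg$transferred, names(ref_reg)]
  rownames(carried) <- NULL
  expect_identical(carried, ref_reg)
})
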