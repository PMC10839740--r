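# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small reference + target generator configuration (2 regions, 6 sites)
small_config <- function(n_rois = 2, ...) {
  cohort_config(
    n_rois = n_rois, n_sites_ref = 6, subjects_per_site_ref = 60,
    target_waves = data.frame(
      wave = c("w1", "w2", "w3"), scanner = c("sA", "sB", "sB"),
      lo = c(6, 8.6, 13), hi = c(10.7, 12, 17), n = c(500L, 500L, 500L),
      age_dist = c("uniform", "triangular", "uniform"),
      stringsAsFactors = FALSE),
    ...
  )
}

quick_control <- function(seed = 1L, chains = 1, warmup = 300, iter = 300) {
  hbr_control(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

# reference cohort + converged fit shared across test files
small_ref <- function() fixture("small_ref", function() {
  cfg <- small_config()
  sim <- simulate_reference_cohort(cfg, seed = 11)
  fit <- suppressWarnings(
    hbr_fit(sim$cohort, control = quick_control(5, chains = 2)))
  list(cfg = cfg, cohort = sim$cohort, truth = sim$truth, fit = fit)
})

small_target <- function() fixture("small_target", function() {
  simulate_target_cohort(small_config(), seed = 12)
})

# a deterministic model carrying the generative truth: degenerate posterior
# (zero parameter variance, noise variance = sigma^2 + omega^2), so that
# predictions equal the true batch lines exactly
model_from_truth <- function(truth) {
  bp <- truth$batch_params
  rois <- unique(bp$roi)
  roi_fits <- lapply(rois, function(r) {
    p <- bp[bp$roi == r, ]
    s2 <- p$sigma^2 + truth$omega^2
    list(
      batch = data.frame(
        batch = p$batch, n = NA_real_,
        alpha_mean = p$alpha, beta_mean = p$beta,
        alpha_var = 0, beta_var = 0, alphabeta_cov = 0,
        sigma2_mean = s2, sigma_mean = sqrt(s2),
        stringsAsFactors = FALSE),
      hyper = data.frame(), rhat = NA_real_, converged = TRUE)
  })
  names(roi_fits) <- rois
  structure(
    list(rois = roi_fits, roi_names = rois,
         transform = age_transform(center = 0, scale = 1),
         batch_vars = truth$batch_vars,
         batch_keys = sort(unique(bp$batch)),
         control = NULL,
         converged = stats::setNames(rep(TRUE, length(rois)), rois),
         n_obs = 0L),
    class = "hbr_model")
}
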