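#' Configuration for the synthetic multi-site cohort generator
#'
#' Defines the generative truth for a synthetic reference cohort (many sites
#' with heterogeneous age windows spanning childhood to old age) and a
#' longitudinal target cohort (three measurement waves on two scanners over a
#' narrow developmental age range), mimicking the structure of multi-site
#' cortical-thickness studies. Regional thickness for scan \eqn{i} in batch
#' \eqn{b} (a site-by-sex or wave-by-sex cell) and region \eqn{r} is
#' \deqn{y = \alpha_{b,r} + \beta_{b,r}\,\mathrm{age} + u_j + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma_{b,r}^2),}
#' with batch intercepts/slopes/log residual SDs drawn around per-region
#' global values, a subject-level random intercept \eqn{u_j} shared across
#' repeated measurements, and residual SD scaling with inverse region area.
#'
#' @param n_rois number of cortical regions.
#' @param roi_names region labels (length `n_rois`).
#' @param roi_area per-region positive surface area (arbitrary units);
#'   defaults to a geometric spread, as parcel areas vary over an order of
#'   magnitude.
#' @param n_sites_ref,subjects_per_site_ref reference-cohort scale.
#' @param mu_alpha,mu_beta per-region global intercept (mm, at age 0) and age
#'   slope (mm/year; negative, cortex thins with age).
#' @param sex_offset per-region additive intercept shift (mm) applied to males.
#' @param tau_alpha,tau_beta between-batch SDs of intercept (mm) and slope
#'   (mm/year).
#' @param sigma0 per-region baseline residual SD (mm) at the mean region area.
#' @param tau_logsigma between-batch SD of log residual SD.
#' @param area_noise_exponent power `a` in
#'   `sigma ~ sigma0 * (area/mean(area))^(-a)`; positive means smaller regions
#'   are noisier.
#' @param omega SD (mm) of the subject-level random intercept, constant
#'   across waves.
#' @param target_waves data frame with columns `wave`, `scanner`, `lo`, `hi`
#'   (age window, years), `n` (scans) and `age_dist`
#'   (`"uniform"`/`"triangular"`). The default gives three waves on two
#'   scanners, waves 2 and 3 sharing a scanner, a peaked wave-2 age
#'   distribution, and an overlap window populated in both waves 1 and 2.
#' @param overlap_window age window (years) in which waves 1 and 2 overlap.
#' @param longitudinal_fraction fraction of wave-1 subjects measured at all
#'   three waves (same subject id and random intercept, strictly increasing
#'   age).
#' @param wave3_offset additive wave-3 intercept shift (mm) mimicking, e.g.,
#'   a scanner software upgrade; 0 by default.
#' @param scanner_offsets named numeric vector of deterministic additive
#'   intercept shifts (mm) per scanner, for controlled site-effect
#'   experiments; unnamed scanners get 0.
#' @param preterm_fraction fraction of target subjects labeled preterm.
#' @param delta per-region preterm mean shift (mm), mixed signs by default.
#'
#' @return an object of class `hbr_cohort_config` (validated list).
#' @seealso [simulate_reference_cohort()], [simulate_target_cohort()]
#' @export
cohort_config <- function(n_rois = 10,
                          roi_names = sprintf("r%02d", seq_len(n_rois)),
                          roi_area = NULL,
                          n_sites_ref = 20,
                          subjects_per_site_ref = 150,
                          mu_alpha = NULL,
                          mu_beta = NULL,
                          sex_offset = NULL,
                          tau_alpha = 0.08,
                          tau_beta = 0.0015,
                          sigma0 = NULL,
                          tau_logsigma = 0.12,
                          area_noise_exponent = 0.3,
                          omega = 0.08,
                          target_waves = NULL,
                          overlap_window = c(8.6, 10.7),
                          longitudinal_fraction = 0.15,
                          wave3_offset = 0,
                          scanner_offsets = NULL,
                          preterm_fraction = 0.054,
                          delta = NULL) {
  roi_area <- roi_area %||% exp(seq(log(150), log(2500), length.out = n_rois))
  mu_alpha <- mu_alpha %||% seq(2.9, 3.6, length.out = n_rois)
  mu_beta <- mu_beta %||% seq(-0.008, -0.018, length.out = n_rois)
  sex_offset <- sex_offset %||% rep(0.03, n_rois)
  sigma0 <- sigma0 %||% rep(0.16, n_rois)
  delta <- delta %||% {
    d <- rep(0, n_rois)
    nz <- intersect(seq_len(n_rois), c(2L, 4L, 7L, 9L))
    d[nz] <- c(0.20, -0.25, -0.15, 0.12)[seq_along(nz)]
    d
  }
  target_waves <- target_waves %||% data.frame(
    wave = c("w1", "w2", "w3"),
    scanner = c("scannerA", "scannerB", "scannerB"),
    lo = c(6, 8.6, 13),
    hi = c(10.7, 12, 17),
    n = c(1600L, 2600L, 2400L),
    age_dist = c("uniform", "triangular", "uniform"),
    stringsAsFactors = FALSE
  )

  cfg <- list(
    n_rois = as.integer(n_rois), roi_names = as.character(roi_names),
    roi_area = as.numeric(roi_area),
    n_sites_ref = as.integer(n_sites_ref),
    subjects_per_site_ref = as.integer(subjects_per_site_ref),
    mu_alpha = as.numeric(mu_alpha), mu_beta = as.numeric(mu_beta),
    sex_offset = as.numeric(sex_offset),
    tau_alpha = tau_alpha, tau_beta = tau_beta,
    sigma0 = as.numeric(sigma0), tau_logsigma = tau_logsigma,
    area_noise_exponent = area_noise_exponent, omega = omega,
    target_waves = target_waves, overlap_window = as.numeric(overlap_window),
    longitudinal_fraction = longitudinal_fraction,
    wave3_offset = wave3_offset, scanner_offsets = scanner_offsets,
    preterm_fraction = preterm_fraction, delta = as.numeric(delta)
  )
  class(cfg) <- "hbr_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_len <- function(field) {
    if (length(cfg[[field]]) != cfg$n_rois)
      stop_field(field, sprintf("must have length n_rois = %d", cfg$n_rois))
  }
  for (f in c("roi_names", "roi_area", "mu_alpha", "mu_beta", "sex_offset",
              "sigma0", "delta")) chk_len(f)
  if (any(cfg$roi_area <= 0)) stop_field("roi_area", "must be > 0")
  if (any(cfg$sigma0 <= 0)) stop_field("sigma0", "must be > 0")
  for (f in c("tau_alpha", "tau_beta", "tau_logsigma", "omega")) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop_field(f, "must be a single value >= 0")
  }
  for (f in c("longitudinal_fraction", "preterm_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0, 1]")
  }
  tw <- cfg$target_waves
  need <- c("wave", "scanner", "lo", "hi", "n", "age_dist")
  if (!all(need %in% names(tw)))
    stop_field("target_waves", paste("needs columns", paste(need, collapse = ", ")))
  if (any(tw$lo >= tw$hi)) stop_field("target_waves", "need lo < hi per wave")
  if (length(unique(tw$scanner)) < 2)
    stop_field("target_waves", "need at least 2 scanners")
  if (nrow(tw) >= 3 && tw$scanner[2] != tw$scanner[3])
    stop_field("target_waves", "waves 2 and 3 must share a scanner")
  if (nrow(tw) >= 2 && tw$scanner[1] == tw$scanner[2])
    stop_field("target_waves", "wave 1 must use a distinct scanner")
  ow <- cfg$overlap_window
  if (length(ow) != 2 || ow[1] >= ow[2])
    stop_field("overlap_window", "must be an increasing [lo, hi] pair")
  so <- cfg$scanner_offsets
  if (!is.null(so) && (!is.numeric(so) || is.null(names(so)) ||
                       !all(names(so) %in% tw$scanner)))
    stop_field("scanner_offsets", "must be numeric, named by target scanners")
  invisible(cfg)
}

# Per-batch residual SD before the batch log-SD deviation: baseline scaled by
# inverse area.
roi_base_sigma <- function(cfg) {
  cfg$sigma0 * (cfg$roi_area / mean(cfg$roi_area))^(-cfg$area_noise_exponent)
}

# Draw batch-level (alpha, beta, sigma) for one batch key across all ROIs.
draw_batch_params <- function(cfg, batch, sex) {
  base_sig <- roi_base_sigma(cfg)
  data.frame(
    batch = batch,
    roi = cfg$roi_names,
    alpha = cfg$mu_alpha + ifelse(sex == "M", cfg$sex_offset, 0) +
      stats::rnorm(cfg$n_rois, 0, cfg$tau_alpha),
    beta = cfg$mu_beta + stats::rnorm(cfg$n_rois, 0, cfg$tau_beta),
    sigma = base_sig * exp(stats::rnorm(cfg$n_rois, 0, cfg$tau_logsigma)),
    stringsAsFactors = FALSE
  )
}

# Assemble thickness columns given rows (age, batch, u) and batch truth.
fill_thickness <- function(rows, bp, cfg) {
  key <- paste(rows$batch, rep(cfg$roi_names, each = nrow(rows)))
  lut <- stats::setNames(seq_len(nrow(bp)), paste(bp$batch, bp$roi))
  for (r in seq_len(cfg$n_rois)) {
    idx <- lut[paste(rows$batch, cfg$roi_names[r])]
    y <- bp$alpha[idx] + bp$beta[idx] * rows$age + rows$u +
      stats::rnorm(nrow(rows), 0, bp$sigma[idx])
    rows[[paste0("roi_", cfg$roi_names[r])]] <- y
  }
  rows
}

new_truth <- function(batch_params, subjects, cfg, batch_vars,
                      has_preterm = FALSE) {
  structure(
    list(batch_params = batch_params, subjects = subjects,
         delta = stats::setNames(if (has_preterm) cfg$delta
                                 else rep(0, cfg$n_rois), cfg$roi_names),
         omega = cfg$omega, batch_vars = batch_vars, config = cfg),
    class = "hbr_truth"
  )
}

#' Simulate a multi-site reference cohort
#'
#' One scan per subject across `n_sites_ref` sites whose age windows jointly
#' cover childhood through old age (site 1 always spans the developmental
#' target range). Batches are site-by-sex cells with heterogeneous
#' intercepts, slopes and residual SDs. Returns the cohort together with the
#' full generative truth for recovery and calibration tests.
#'
#' @param config an [cohort_config()] object.
#' @param seed integer seed; identical config and seed give identical tables.
#' @return list with elements `cohort` (data frame, one row per scan, regions
#'   in `roi_*` columns) and `truth` (class `hbr_truth`: realized per-batch
#'   parameters, subject random intercepts, preterm shifts).
#' @export
simulate_reference_cohort <- function(config, seed = 1L) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(derive_seed(seed, 11L))

  ns <- cfg$n_sites_ref
  centers <- seq(12, 92, length.out = ns)
  widths <- stats::runif(ns, 20, 50)
  lo <- pmax(5, centers - widths / 2)
  hi <- pmin(100, centers + widths / 2)

  rows_list <- vector("list", ns)
  bp_list <- list()
  subj_list <- list()
  for (s in seq_len(ns)) {
    site <- sprintf("site%02d", s)
    n <- cfg$subjects_per_site_ref
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- stats::runif(n, lo[s], hi[s])
    u <- stats::rnorm(n, 0, cfg$omega)
    sid <- sprintf("%s_s%04d", site, seq_len(n))
    rows <- data.frame(
      subject_id = sid, site = site, scanner = site, wave = NA_character_,
      sex = sex, age = age, group = "control", u = u,
      stringsAsFactors = FALSE
    )
    rows$batch <- make_batch_key(rows, c("site", "sex"))
    for (sx in c("F", "M")) {
      bkey <- paste(site, sx, sep = ":")
      bp_list[[bkey]] <- draw_batch_params(cfg, bkey, sx)
    }
    bp_site <- do.call(rbind, bp_list[paste(site, c("F", "M"), sep = ":")])
    rows <- fill_thickness(rows, bp_site, cfg)
    rows_list[[s]] <- rows
    subj_list[[s]] <- data.frame(subject_id = sid, u = u,
                                 stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows_list)
  cohort$u <- NULL
  cohort$batch <- NULL
  cohort$row_id <- seq_len(nrow(cohort))
  cohort <- cohort[c("row_id", setdiff(names(cohort), "row_id"))]
  rownames(cohort) <- NULL

  truth <- new_truth(do.call(rbind, bp_list), do.call(rbind, subj_list),
                     cfg, batch_vars = c("site", "sex"))
  rownames(truth$batch_params) <- NULL
  list(cohort = cohort, truth = truth)
}

#' Simulate the longitudinal target cohort
#'
#' Three measurement waves on two scanners over a narrow developmental age
#' range. Batch parameters are drawn per scanner-by-sex cell (waves on the
#' same scanner share them); an optional `wave3_offset` adds a wave-specific
#' intercept shift, mimicking a software upgrade. A fraction of subjects is
#' measured at all three waves with a shared subject-level random intercept
#' and strictly increasing ages; a fraction is labeled preterm and receives
#' per-region mean shifts `delta`. Waves 1 and 2 both contain scans in the
#' configured overlapping age window.
#'
#' @inheritParams simulate_reference_cohort
#' @return list with `cohort` and `truth`; truth batch parameters are keyed
#'   per wave-by-sex cell (wave-3 rows include `wave3_offset`).
#' @export
simulate_target_cohort <- function(config, seed = 2L) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(derive_seed(seed, 23L))
  tw <- cfg$target_waves
  nw <- nrow(tw)

  # scanner x sex heterogeneity; wave-level truth derived from it
  scan_bp <- list()
  for (sc in unique(tw$scanner)) {
    off <- if (!is.null(cfg$scanner_offsets) &&
               sc %in% names(cfg$scanner_offsets))
      cfg$scanner_offsets[[sc]] else 0
    for (sx in c("F", "M")) {
      bp <- draw_batch_params(cfg, paste(sc, sx, sep = ":"), sx)
      bp$alpha <- bp$alpha + off
      scan_bp[[paste(sc, sx, sep = ":")]] <- bp
    }
  }

  n_long <- round(cfg$longitudinal_fraction * tw$n[1])
  if (nw < 3) n_long <- 0

  subj_rows <- list()
  subj_tab <- list()
  next_id <- 1L

  if (n_long > 0) {
    # ages within each wave window, strictly increasing per subject
    a1 <- stats::runif(n_long, max(tw$lo[1], 6.2), min(tw$hi[1], 8.9))
    a2 <- a1 + stats::runif(n_long, 2.6, 3.1)
    a2 <- pmin(pmax(a2, tw$lo[2]), tw$hi[2])
    a3 <- a2 + stats::runif(n_long, 3.0, 4.8)
    a3 <- pmin(pmax(a3, tw$lo[3]), tw$hi[3])
    sid <- sprintf("T%05d", seq_len(n_long) + next_id - 1L)
    next_id <- next_id + n_long
    sex <- sample(c("F", "M"), n_long, replace = TRUE)
    u <- stats::rnorm(n_long, 0, cfg$omega)
    for (w in 1:3) {
      subj_rows[[length(subj_rows) + 1L]] <- data.frame(
        subject_id = sid, site = tw$scanner[w], scanner = tw$scanner[w],
        wave = tw$wave[w], sex = sex, age = list(a1, a2, a3)[[w]],
        group = "control", u = u, longitudinal = TRUE,
        stringsAsFactors = FALSE
      )
    }
    subj_tab[[length(subj_tab) + 1L]] <-
      data.frame(subject_id = sid, u = u, stringsAsFactors = FALSE)
  }

  for (w in seq_len(nw)) {
    n_cs <- tw$n[w] - if (w <= 3) n_long else 0L
    if (n_cs <= 0) next
    age <- if (tw$age_dist[w] == "triangular") {
      rtriangular(n_cs, tw$lo[w], tw$hi[w],
                  mode = tw$lo[w] + 0.35 * (tw$hi[w] - tw$lo[w]))
    } else {
      stats::runif(n_cs, tw$lo[w], tw$hi[w])
    }
    sid <- sprintf("T%05d", seq_len(n_cs) + next_id - 1L)
    next_id <- next_id + n_cs
    sex <- sample(c("F", "M"), n_cs, replace = TRUE)
    u <- stats::rnorm(n_cs, 0, cfg$omega)
    subj_rows[[length(subj_rows) + 1L]] <- data.frame(
      subject_id = sid, site = tw$scanner[w], scanner = tw$scanner[w],
      wave = tw$wave[w], sex = sex, age = age, group = "control", u = u,
      longitudinal = FALSE, stringsAsFactors = FALSE
    )
    subj_tab[[length(subj_tab) + 1L]] <-
      data.frame(subject_id = sid, u = u, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, subj_rows)
  subjects <- do.call(rbind, subj_tab)

  # preterm labels per subject
  uniq <- unique(rows$subject_id)
  n_pre <- round(cfg$preterm_fraction * length(uniq))
  pre_ids <- if (n_pre > 0) sample(uniq, n_pre) else character(0)
  rows$group[rows$subject_id %in% pre_ids] <- "preterm"

  rows$batch <- make_batch_key(rows, c("scanner", "sex"))
  rows <- fill_thickness(rows, do.call(rbind, scan_bp), cfg)

  roi_col <- paste0("roi_", cfg$roi_names)
  # wave-3 intercept shift and preterm shifts enter the observed values
  if (cfg$wave3_offset != 0 && nw >= 3) {
    w3 <- rows$wave == tw$wave[3]
    rows[w3, roi_col] <- rows[w3, roi_col] + cfg$wave3_offset
  }
  if (length(pre_ids) > 0) {
    pr <- rows$group == "preterm"
    rows[pr, roi_col] <- sweep(rows[pr, roi_col, drop = FALSE], 2,
                               cfg$delta, `+`)
  }

  # wave x sex truth: copy the scanner-cell parameters, add wave-3 offset
  bp_wave <- list()
  for (w in seq_len(nw)) {
    for (sx in c("F", "M")) {
      bp <- scan_bp[[paste(tw$scanner[w], sx, sep = ":")]]
      bp$batch <- paste(tw$wave[w], sx, sep = ":")
      if (w == 3 && nw >= 3) bp$alpha <- bp$alpha + cfg$wave3_offset
      bp_wave[[paste(tw$wave[w], sx, sep = ":")]] <- bp
    }
  }

  cohort <- rows
  cohort$u <- NULL
  cohort$batch <- NULL
  cohort$row_id <- seq_len(nrow(cohort))
  cohort <- cohort[c("row_id", setdiff(names(cohort), "row_id"))]
  rownames(cohort) <- NULL

  truth <- new_truth(do.call(rbind, bp_wave), subjects, cfg,
                     batch_vars = c("wave", "sex"),
                     has_preterm = length(pre_ids) > 0)
  truth$scanner_params <- do.call(rbind, scan_bp)
  rownames(truth$batch_params) <- NULL
  list(cohort = cohort, truth = truth)
}

#' Ground-truth deviation scores from the generative parameters
#'
#' Oracle z-scores for calibration tests:
#' \eqn{z = (y - \alpha_b - \beta_b\,\mathrm{age}) / \sqrt{\sigma_b^2 + \omega^2}}
#' computed for control scans of non-longitudinal subjects, which are exactly
#' standard normal by construction (the subject random intercept is folded
#' into the denominator because each such subject contributes one scan).
#'
#' @param cohort a generated cohort table.
#' @param truth the matching `hbr_truth` object.
#' @return data frame of covariates plus `z_<roi>` columns.
#' @export
true_zscores <- function(cohort, truth) {
  stopifnot(inherits(truth, "hbr_truth"))
  keep <- cohort$group %in% "control"
  if ("longitudinal" %in% names(cohort)) keep <- keep & !cohort$longitudinal
  dat <- cohort[keep, , drop = FALSE]
  dat$batch <- make_batch_key(dat, truth$batch_vars)
  bp <- truth$batch_params
  missing_b <- setdiff(unique(dat$batch), unique(bp$batch))
  if (length(missing_b) > 0)
    stop(sprintf("batch not covered by truth record: %s",
                 paste(missing_b, collapse = ", ")), call. = FALSE)
  lut <- stats::setNames(seq_len(nrow(bp)), paste(bp$batch, bp$roi))
  out <- dat[c("row_id", "subject_id", "wave", "scanner", "sex", "age", "group")]
  for (r in truth$config$roi_names) {
    idx <- lut[paste(dat$batch, r)]
    denom <- sqrt(bp$sigma[idx]^2 + truth$omega^2)
    out[[paste0("z_", r)]] <-
      (dat[[paste0("roi_", r)]] - bp$alpha[idx] - bp$beta[idx] * dat$age) / denom
  }
  rownames(out) <- NULL
  out
}

#' Empirical hyperparameters implied by a generative truth record
#'
#' Maps the realized batch-level parameters onto the scale the fitted model
#' works on: the age covariate standardized by `transform`, the subject
#' random intercept folded into the residual SD (each reference subject is
#' scanned once, so the model's batch noise estimates
#' \eqn{\sqrt{\sigma_b^2 + \omega^2}}). Returns the across-batch mean and SD
#' of intercepts, slopes and log residual SDs per region — the finite-sample
#' truth a converged hierarchical fit should recover.
#'
#' @param truth an `hbr_truth` object.
#' @param transform an age-standardization transform (see [age_transform()]).
#' @return data frame: one row per region and hyperparameter (`mu_alpha`,
#'   `tau_alpha`, `mu_beta`, `tau_beta`, `mu_logsigma`, `tau_logsigma`) with
#'   the empirical value.
#' @export
implied_hyperparameters <- function(truth, transform) {
  stopifnot(inherits(truth, "hbr_truth"))
  bp <- truth$batch_params
  ctr <- transform$center
  scl <- transform$scale
  out <- list()
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  for (r in unique(bp$roi)) {
    p <- bp[bp$roi == r, ]
    a_std <- p$alpha + p$beta * ctr        # intercept at standardized age 0
    b_std <- p$beta * scl
    ls <- 0.5 * log(p$sigma^2 + truth$omega^2)
    out[[r]] <- data.frame(
      roi = r,
      hyper = c("mu_alpha", "tau_alpha", "mu_beta", "tau_beta",
                "mu_logsigma", "tau_logsigma"),
      value = c(mean(a_std), sd_pop(a_std), mean(b_std), sd_pop(b_std),
                mean(ls), sd_pop(ls)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
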