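#' Age standardization transform
#'
#' The model works on a standardized age covariate
#' `x = (age - center) / scale`, with center/scale fitted on the reference
#' training data and frozen into the model, so that prior scales are
#' invariant to the covariate's units and range.
#'
#' @param ages numeric ages in years (to fit the transform), or `NULL` when
#'   supplying `center`/`scale` directly.
#' @param center,scale transform parameters (years); `scale` must be > 0.
#' @return object of class `hbr_age_transform`.
#' @export
age_transform <- function(ages = NULL, center = NULL, scale = NULL) {
  if (!is.null(ages)) {
    center <- mean(ages)
    scale <- stats::sd(ages)
  }
  if (is.null(scale) || is.null(center) || !is.finite(scale) || scale <= 0)
    stop_field("scale", "age-transform scale must be > 0")
  structure(list(center = center, scale = scale), class = "hbr_age_transform")
}

#' @rdname age_transform
#' @param transform an `hbr_age_transform`.
#' @export
standardize_age <- function(ages, transform) {
  stopifnot(inherits(transform, "hbr_age_transform"))
  (ages - transform$center) / transform$scale
}

#' @rdname age_transform
#' @param x standardized covariate values.
#' @export
unstandardize_age <- function(x, transform) {
  stopifnot(inherits(transform, "hbr_age_transform"))
  x * transform$scale + transform$center
}

#' Hyperprior specification
#'
#' Priors on the six hyperparameters of the hierarchy: Normal priors on the
#' means (`mu_alpha`, `mu_beta`, `mu_logsigma`) and half-normal or
#' zero-truncated Normal priors on the between-batch SDs (`tau_alpha`,
#' `tau_beta`, `tau_logsigma`). Each element is a list with `dist`
#' (`"normal"`, `"halfnormal"`, `"truncnormal"`), `location` and `scale`.
#' All scales must be positive. Priors are expressed on the standardized-age
#' scale.
#'
#' @param mu_alpha,tau_alpha,mu_beta,tau_beta,mu_logsigma,tau_logsigma prior
#'   component lists, see Description.
#' @return object of class `hbr_priors`.
#' @export
prior_spec <- function(mu_alpha, tau_alpha, mu_beta, tau_beta,
                       mu_logsigma, tau_logsigma) {
  pr <- list(mu_alpha = mu_alpha, tau_alpha = tau_alpha,
             mu_beta = mu_beta, tau_beta = tau_beta,
             mu_logsigma = mu_logsigma, tau_logsigma = tau_logsigma)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (is.null(p$dist) || is.null(p$scale) || p$scale <= 0)
      stop_field(nm, "prior needs a distribution and a positive scale")
    if (p$dist %in% c("normal", "truncnormal") && is.null(p$location))
      stop_field(nm, "normal-family prior needs a location")
    if (p$dist == "halfnormal") pr[[nm]]$location <- 0
    if (startsWith(nm, "tau") && !p$dist %in% c("halfnormal", "truncnormal"))
      stop_field(nm, "tau priors must be halfnormal or zero-truncated normal")
    if (startsWith(nm, "mu") && p$dist != "normal")
      stop_field(nm, "mu priors must be normal")
  }
  structure(pr, class = "hbr_priors")
}

#' Default weakly-informative hyperpriors
#'
#' Scale-aware diffuse defaults for cold-start fits:
#' `mu_alpha ~ N(mean(y), 10 sd(y))`, `mu_beta ~ N(0, 10 sd(y))`,
#' `mu_logsigma ~ N(log sd(y), 2)`, `tau_alpha, tau_beta ~
#' HalfNormal(5 sd(y))`, `tau_logsigma ~ HalfNormal(1)`; slopes are on the
#' standardized-age scale, and every location/scale parameter scales with
#' the data so that deviation scores are invariant to the measurement unit.
#'
#' @param y observed thickness values for one region (mm).
#' @return an [prior_spec()] object.
#' @export
default_priors <- function(y) {
  m <- mean(y); s <- max(stats::sd(y), 1e-6)
  prior_spec(
    mu_alpha = list(dist = "normal", location = m, scale = 10 * s),
    tau_alpha = list(dist = "halfnormal", scale = 5 * s),
    mu_beta = list(dist = "normal", location = 0, scale = 10 * s),
    tau_beta = list(dist = "halfnormal", scale = 5 * s),
    mu_logsigma = list(dist = "normal", location = log(s), scale = 2),
    tau_logsigma = list(dist = "halfnormal", scale = 1)
  )
}

#' Sampler settings
#'
#' @param chains number of MCMC chains.
#' @param warmup,iter warmup and retained iterations per chain.
#' @param seed integer seed; identical settings reproduce identical draws.
#' @param adapt_interval warmup interval for Metropolis step-size adaptation.
#' @return list of class `hbr_control`.
#' @export
hbr_control <- function(chains = 2, warmup = 1000, iter = 1000, seed = 1L,
                        adapt_interval = 50) {
  stopifnot(chains >= 1, warmup >= adapt_interval, iter >= 4)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval)),
            class = "hbr_control")
}

check_cohort_for_fit <- function(cohort, rois, batch_vars) {
  cols <- paste0("roi_", rois)
  missing_cols <- setdiff(c("age", "sex", batch_vars, cols), names(cohort))
  if (length(missing_cols) > 0)
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (cc in cols) {
    bad <- which(!is.finite(cohort[[cc]]))
    if (length(bad) > 0)
      stop(sprintf("non-finite thickness in %s at row(s) %s; only complete data can be fitted",
                   cc, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the hierarchical Bayesian normative model on a reference cohort
#'
#' Per region, fits the linear hierarchical model
#' \deqn{y = \alpha_b + \beta_b x + \epsilon,\quad \epsilon \sim N(0, \sigma_b^2)}
#' with batch-specific intercepts, slopes and log residual SDs partially
#' pooled through Normal hyperdistributions
#' (\eqn{\alpha_b \sim N(\mu_\alpha, \tau_\alpha^2)} etc.), where `x` is
#' standardized age and a batch is one cell of the variables in
#' `batch_vars` (site-by-sex by default). Sampling is Metropolis-within-Gibbs
#' with conjugate block updates; convergence is gated on split-chain
#' R-hat < 1.05 for all stored parameters.
#'
#' @param cohort cohort data frame with `age`, `sex`, the batch variables and
#'   `roi_*` thickness columns (no missing values).
#' @param rois region names to fit (default: all `roi_*` columns).
#' @param batch_vars columns crossed to form batches.
#' @param priors an [prior_spec()], a named per-region list of them, or
#'   `NULL` for [default_priors()] per region.
#' @param control an [hbr_control()].
#' @param transform an [age_transform()] to reuse; default fitted on
#'   `cohort$age`.
#' @param freeze_hypers keep hyperparameters fixed at their prior locations
#'   instead of sampling them (point-estimate transfer mode).
#' @return object of class `hbr_model`: per-region posterior draws and
#'   summaries, batch registry, the frozen age transform and diagnostics.
#' @examples
#' cfg <- cohort_config(n_rois = 2, n_sites_ref = 4, subjects_per_site_ref = 40)
#' ref <- simulate_reference_cohort(cfg, seed = 1)
#' fit <- hbr_fit(ref$cohort, control = hbr_control(chains = 2, warmup = 200,
#'                                                  iter = 200, seed = 1))
#' fit
#' @export
hbr_fit <- function(cohort, rois = NULL, batch_vars = c("site", "sex"),
                    priors = NULL, control = hbr_control(),
                    transform = NULL, freeze_hypers = FALSE) {
  rois <- rois %||% roi_names_of(cohort)
  if (length(rois) == 0) stop("no roi_* columns found", call. = FALSE)
  check_cohort_for_fit(cohort, rois, batch_vars)
  key <- make_batch_key(cohort, batch_vars)
  batch_keys <- sort(unique(key))
  tab <- table(key)
  small <- names(tab)[tab < 3]
  if (length(small) > 0)
    stop(sprintf("batch(es) with fewer than 3 observations: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  transform <- transform %||% age_transform(cohort$age)
  x <- standardize_age(cohort$age, transform)
  batch_idx <- match(key, batch_keys)

  roi_fits <- list()
  roi_priors <- list()
  for (r in rois) {
    y <- cohort[[paste0("roi_", r)]]
    pr <- if (is.null(priors)) default_priors(y)
          else if (inherits(priors, "hbr_priors")) priors
          else priors[[r]]
    if (!inherits(pr, "hbr_priors"))
      stop_field("priors", sprintf("no prior spec for region %s", r))
    roi_priors[[r]] <- pr
    ctl <- control
    ctl$seed <- derive_seed(control$seed, match(r, rois))
    roi_fits[[r]] <- fit_hbr_roi(x, y, batch_idx, batch_keys, pr, ctl,
                                 freeze_hypers = freeze_hypers)
  }
  conv <- vapply(roi_fits, `[[`, TRUE, "converged")
  if (!all(conv))
    warning(sprintf("convergence flag false (split R-hat >= 1.05) for region(s): %s",
                    paste(names(conv)[!conv], collapse = ", ")), call. = FALSE)
  structure(
    list(rois = roi_fits, roi_names = rois, priors = roi_priors,
         transform = transform, batch_vars = batch_vars,
         batch_keys = batch_keys, control = control,
         freeze_hypers = freeze_hypers, converged = conv,
         n_obs = nrow(cohort)),
    class = "hbr_model"
  )
}

# registry of batch summaries for a model (adapted models override this)
batch_registry <- function(model, roi) {
  model$rois[[roi]]$batch
}

#' Posterior predictive mean and SD
#'
#' For each row of `newdata`, looks up the row's batch and returns the
#' posterior predictive mean `E[alpha_b + beta_b x]` and, by default, the
#' full predictive SD combining posterior parameter uncertainty with the
#' posterior mean noise variance:
#' `pred_sd^2 = Var(alpha_b + beta_b x) + E[sigma_b^2]`. With
#' `sd_mode = "noise_only"` the parameter-uncertainty term is dropped.
#'
#' @param object an `hbr_model` or adapted model.
#' @param newdata data frame with `age` and the model's batch variables.
#' @param rois regions to predict (default: all fitted).
#' @param sd_mode `"full"` or `"noise_only"`.
#' @param ... unused.
#' @return list with matrices `mean` and `sd` (rows of `newdata` by region).
#' @export
predict.hbr_model <- function(object, newdata, rois = NULL,
                              sd_mode = c("full", "noise_only"), ...) {
  sd_mode <- match.arg(sd_mode)
  rois <- rois %||% object$roi_names
  key <- make_batch_key(newdata, object$batch_vars)
  x <- standardize_age(newdata$age, object$transform)
  n <- nrow(newdata)
  pm <- matrix(NA_real_, n, length(rois), dimnames = list(NULL, rois))
  ps <- pm
  for (r in rois) {
    reg <- batch_registry(object, r)
    idx <- match(key, reg$batch)
    if (anyNA(idx)) {
      unk <- unique(key[is.na(idx)])
      stop(sprintf("unknown batch(es): %s; transfer/adapt the model to these batches first",
                   paste(unk, collapse = ", ")), call. = FALSE)
    }
    pm[, r] <- reg$alpha_mean[idx] + reg$beta_mean[idx] * x
    v_par <- reg$alpha_var[idx] + 2 * x * reg$alphabeta_cov[idx] +
      x^2 * reg$beta_var[idx]
    v <- if (sd_mode == "full") v_par + reg$sigma2_mean[idx]
         else reg$sigma2_mean[idx]
    ps[, r] <- sqrt(v)
  }
  list(mean = pm, sd = ps)
}

#' @export
print.hbr_model <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian normative model (%d region%s)\n",
              length(x$roi_names), if (length(x$roi_names) == 1) "" else "s"))
  cat(sprintf("  batches: %d cells of %s; %d training scans\n",
              length(x$batch_keys), paste(x$batch_vars, collapse = " x "),
              x$n_obs))
  cat(sprintf("  age transform: center %.2f y, scale %.2f y\n",
              x$transform$center, x$transform$scale))
  cat(sprintf("  sampler: %d chain(s) x %d draws (+%d warmup), seed %d\n",
              x$control$chains, x$control$iter, x$control$warmup,
              x$control$seed))
  cat(sprintf("  converged (split R-hat < 1.05): %d/%d regions\n",
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' @export
summary.hbr_model <- function(object, ...) {
  hs <- hyperposterior_summary(object)
  rh <- vapply(object$rois, function(f) max(f$rhat, na.rm = TRUE), 0)
  out <- list(hyper = hs, max_rhat = rh, converged = object$converged)
  class(out) <- "summary.hbr_model"
  out
}

#' @export
print.summary.hbr_model <- function(x, ...) {
  cat("Hyperparameter posterior summaries (standardized-age scale):\n")
  print(x$hyper, row.names = FALSE, digits = 4)
  cat("\nMax split R-hat per region:\n")
  print(round(x$max_rhat, 3))
  invisible(x)
}

#' Posterior-mean batch coefficients
#'
#' @param object an `hbr_model`.
#' @param scale `"standardized"` (model-internal covariate) or `"natural"`
#'   (intercept at age 0 in mm, slope in mm/year).
#' @param ... unused.
#' @return data frame of per-region, per-batch posterior means for the
#'   intercept, slope and residual SD.
#' @export
coef.hbr_model <- function(object, scale = c("standardized", "natural"), ...) {
  scale <- match.arg(scale)
  out <- lapply(object$roi_names, function(r) {
    reg <- batch_registry(object, r)
    a <- reg$alpha_mean; b <- reg$beta_mean
    if (scale == "natural") {
      b_nat <- b / object$transform$scale
      a <- a - b_nat * object$transform$center
      b <- b_nat
    }
    data.frame(roi = r, batch = reg$batch, n = reg$n, alpha = a, beta = b,
               sigma = reg$sigma_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Deviation scores as model residuals
#'
#' @param object an `hbr_model`.
#' @param newdata cohort rows with observed `roi_*` columns.
#' @param type `"z"` for deviation scores, `"raw"` for `y - pred_mean` (mm).
#' @param ... passed to [predict.hbr_model()].
#' @export
residuals.hbr_model <- function(object, newdata, type = c("z", "raw"), ...) {
  type <- match.arg(type)
  pr <- predict(object, newdata, ...)
  y <- as.matrix(newdata[paste0("roi_", colnames(pr$mean))])
  res <- y - pr$mean
  if (type == "z") res <- res / pr$sd
  colnames(res) <- colnames(pr$mean)
  res
}

#' Simulate thickness values from the Gaussian posterior predictive
#'
#' @param object an `hbr_model`.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param newdata rows (age + batch variables) to simulate for.
#' @param ... passed to [predict.hbr_model()].
#' @return list of `nsim` matrices (rows by regions) of simulated thickness.
#' @export
simulate.hbr_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, ...)
  lapply(seq_len(nsim), function(i) {
    pr$mean + pr$sd * matrix(stats::rnorm(length(pr$mean)), nrow(pr$mean))
  })
}

#' Plot normative centiles for one region and batch
#'
#' Draws the posterior predictive mean and the 5th/95th centile band over an
#' age grid, with observed points overlaid when supplied.
#'
#' @param x an `hbr_model`.
#' @param roi region name (default: first fitted).
#' @param batch batch key (default: first in the registry).
#' @param ages age grid (years).
#' @param cohort optional cohort rows to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hbr_model <- function(x, roi = NULL, batch = NULL, ages = NULL,
                           cohort = NULL, ...) {
  roi <- roi %||% x$roi_names[1]
  reg <- batch_registry(x, roi)
  batch <- batch %||% reg$batch[1]
  if (is.null(ages)) {
    ctr <- x$transform$center; scl <- x$transform$scale
    ages <- seq(ctr - 2 * scl, ctr + 2 * scl, length.out = 100)
  }
  parts <- strsplit(batch, ":", fixed = TRUE)[[1]]
  nd <- data.frame(age = ages)
  for (i in seq_along(x$batch_vars)) nd[[x$batch_vars[i]]] <- parts[i]
  pr <- predict(x, nd, rois = roi)
  q <- stats::qnorm(0.95)
  graphics::plot(ages, pr$mean[, roi], type = "l", lwd = 2,
                 ylim = range(pr$mean[, roi] + q * pr$sd[, roi],
                              pr$mean[, roi] - q * pr$sd[, roi]),
                 xlab = "age (years)", ylab = sprintf("%s thickness (mm)", roi),
                 main = sprintf("normative centiles, batch %s", batch), ...)
  graphics::lines(ages, pr$mean[, roi] + q * pr$sd[, roi], lty = 2)
  graphics::lines(ages, pr$mean[, roi] - q * pr$sd[, roi], lty = 2)
  if (!is.null(cohort)) {
    keep <- make_batch_key(cohort, x$batch_vars) == batch
    graphics::points(cohort$age[keep], cohort[[paste0("roi_", roi)]][keep],
                     pch = 16, cex = 0.4, col = "grey40")
  }
  invisible(x)
}

#' Summarize the hyperparameter posterior
#'
#' Per region and hyperparameter, the posterior mean and SD over draws.
#' SDs are floored at 1e-6 of the corresponding mean scale so that a
#' degenerate draw set can never produce a zero-width transfer prior.
#'
#' @param model a converged `hbr_model`.
#' @return data frame with columns `roi`, `hyper`, `mean`, `sd`.
#' @export
hyperposterior_summary <- function(model) {
  stopifnot(inherits(model, "hbr_model"))
  out <- lapply(model$roi_names, function(r) {
    h <- model$rois[[r]]$hyper
    if (nrow(h) == 0) stop("empty hyperparameter draw set", call. = FALSE)
    floor_sd <- 1e-6 * pmax(abs(h$mean), 1)
    h$sd <- pmax(h$sd, floor_sd)
    cbind(roi = r, h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
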