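# Transfer of the reference hyperposterior to unseen batches.

#' Build informed transfer priors from a hyperposterior summary
#'
#' Each hyperparameter's prior is set to a Normal (zero-truncated Normal for
#' the tau parameters) with the reference posterior mean and SD, so that
#' new-batch parameters are drawn hierarchically from what the reference
#' cohort learned. The approximation keeps only per-hyperparameter means and
#' SDs, which is what makes the models portable across analysis sites
#' without sharing data.
#'
#' @param summary output of [hyperposterior_summary()] (all regions or one).
#' @return named list of [prior_spec()] objects, one per region.
#' @export
transfer_priors <- function(summary) {
  need <- hyper_names
  out <- list()
  for (r in unique(summary$roi)) {
    h <- summary[summary$roi == r, ]
    missing_h <- setdiff(need, h$hyper)
    if (length(missing_h) > 0)
      stop(sprintf("hyperposterior summary for %s is missing: %s", r,
                   paste(missing_h, collapse = ", ")), call. = FALSE)
    g <- function(nm, what) h[[what]][h$hyper == nm]
    mk_mu <- function(nm) list(dist = "normal", location = g(nm, "mean"),
                               scale = g(nm, "sd"))
    mk_tau <- function(nm) list(dist = "truncnormal", location = g(nm, "mean"),
                                scale = g(nm, "sd"))
    out[[r]] <- prior_spec(
      mu_alpha = mk_mu("mu_alpha"), tau_alpha = mk_tau("tau_alpha"),
      mu_beta = mk_mu("mu_beta"), tau_beta = mk_tau("tau_beta"),
      mu_logsigma = mk_mu("mu_logsigma"), tau_logsigma = mk_tau("tau_logsigma")
    )
  }
  out
}

# draw n rows per batch from `pool` under the current RNG state; returns
# integer indices into pool. Batches with exactly n rows are taken whole.
draw_batch_sample <- function(pool, n_per_batch, strategy, batch_vars) {
  key <- make_batch_key(pool, batch_vars)
  take <- integer(0)
  for (b in sort(unique(key))) {
    rows <- which(key == b)
    if (length(rows) < n_per_batch)
      stop(sprintf("batch %s has only %d scans; need %d", b, length(rows),
                   n_per_batch), call. = FALSE)
    if (length(rows) == n_per_batch) {
      take_b <- rows
    } else if (strategy == "random") {
      take_b <- sample(rows, n_per_batch)
    } else {
      # age-uniform: one draw per nonempty equal-width age bin
      ages <- pool$age[rows]
      brk <- seq(min(ages), max(ages), length.out = n_per_batch + 1)
      bin <- pmin(pmax(findInterval(ages, brk, rightmost.closed = TRUE), 1),
                  n_per_batch)
      take_b <- integer(0)
      for (k in unique(bin)) {
        cand <- rows[bin == k]
        take_b <- c(take_b, if (length(cand) == 1) cand else sample(cand, 1))
      }
      short <- n_per_batch - length(take_b)
      if (short > 0) {
        rest <- setdiff(rows, take_b)
        take_b <- c(take_b, if (short >= length(rest)) rest
                            else sample(rest, short))
      }
    }
    take <- c(take, take_b)
  }
  take
}

# rows that must never enter an adaptation set: subjects measured at every
# wave, plus first-wave scans inside the overlapping age window
withheld_validation_rows <- function(cohort, overlap_window) {
  withheld <- rep(FALSE, nrow(cohort))
  if ("wave" %in% names(cohort) && !all(is.na(cohort$wave))) {
    waves <- sort(unique(stats::na.omit(cohort$wave)))
    if (length(waves) >= 3) {
      nw <- tapply(cohort$wave, cohort$subject_id,
                   function(w) length(unique(w)))
      allwave <- names(nw)[nw == length(waves)]
      withheld <- withheld | cohort$subject_id %in% allwave
    }
    if (length(waves) >= 2 && !is.null(overlap_window)) {
      withheld <- withheld | (cohort$wave == waves[1] &
                                cohort$age >= overlap_window[1] &
                                cohort$age <= overlap_window[2])
    }
  }
  withheld
}

#' Sample an adaptation set from a target cohort
#'
#' Draws `n_per_batch` scans per batch without replacement, after first
#' withholding the validation scans (subjects measured at all waves, and
#' first-wave scans inside the overlapping age window) so they can never
#' leak into adaptation. Scans of clinical-group subjects (any `group`
#' other than `"control"`) are likewise kept out of the adaptation pool —
#' the adapted model must describe the normative population — but remain
#' in the evaluation remainder. Strategy `"random"` is a simple random sample;
#' `"age_uniform"` stratifies each batch's age range into `n_per_batch`
#' equal-width bins and draws one scan per nonempty bin (filling any
#' shortfall randomly), giving uniform age coverage of peaked
#' distributions.
#'
#' @param cohort target cohort data frame (must carry `row_id`).
#' @param n_per_batch scans per batch.
#' @param strategy `"random"` or `"age_uniform"`.
#' @param seed integer seed.
#' @param batch_vars columns crossed to form adaptation batches
#'   (default wave-by-sex).
#' @param overlap_window age window withheld from wave 1, or `NULL`.
#' @return object of class `hbr_adaptation_set`: `$data` (adaptation rows),
#'   `$remainder` (evaluation rows), `$withheld` (validation rows), plus the
#'   sampling metadata.
#' @export
sample_adaptation_set <- function(cohort, n_per_batch,
                                  strategy = c("random", "age_uniform"),
                                  seed = 1L,
                                  batch_vars = c("wave", "sex"),
                                  overlap_window = c(8.6, 10.7)) {
  strategy <- match.arg(strategy)
  if (!"row_id" %in% names(cohort)) cohort$row_id <- seq_len(nrow(cohort))
  withheld <- withheld_validation_rows(cohort, overlap_window)
  clinical <- if ("group" %in% names(cohort))
    !(cohort$group %in% "control") else rep(FALSE, nrow(cohort))
  pool <- cohort[!withheld & !clinical, , drop = FALSE]
  key <- make_batch_key(pool, batch_vars)
  short_b <- names(which(table(key) < n_per_batch))
  if (length(short_b) > 0)
    stop(sprintf("batch(es) with fewer than n_per_batch = %d available scans: %s",
                 n_per_batch, paste(short_b, collapse = ", ")), call. = FALSE)
  set.seed(derive_seed(seed, 37L))
  take <- draw_batch_sample(pool, n_per_batch, strategy, batch_vars)
  adat <- pool[sort(take), , drop = FALSE]
  remainder <- cohort[!withheld, , drop = FALSE]
  remainder <- remainder[!remainder$row_id %in% adat$row_id, , drop = FALSE]
  structure(
    list(data = adat, remainder = remainder,
         withheld = cohort[withheld, , drop = FALSE],
         n_per_batch = n_per_batch, strategy = strategy, seed = seed,
         batch_vars = batch_vars, overlap_window = overlap_window),
    class = "hbr_adaptation_set"
  )
}

#' @export
print.hbr_adaptation_set <- function(x, ...) {
  cat(sprintf("Adaptation set: %d scans (%d per %s batch, strategy %s, seed %d)\n",
              nrow(x$data), x$n_per_batch,
              paste(x$batch_vars, collapse = " x "), x$strategy, x$seed))
  cat(sprintf("  remainder (evaluation): %d scans; withheld validation: %d scans\n",
              nrow(x$remainder), nrow(x$withheld)))
  invisible(x)
}

#' Adapt a reference model to unseen batches
#'
#' Re-fits the hierarchy on the adaptation scans only, with the reference
#' model's hyperparameter posterior turned into informed priors by
#' [transfer_priors()]. By default the hyperparameters are re-sampled under
#' those priors jointly with the new-batch parameters, propagating reference
#' uncertainty; `freeze_hypers = TRUE` instead pins them at the reference
#' posterior means. The reference batches' posteriors are carried over
#' untouched; new batches are flagged as transferred. With
#' `prior_only = TRUE` and an empty adaptation table, the stated
#' `new_batches` get their prior (hyperprior-mean) predictive.
#'
#' @param reference a fitted `hbr_model` (reference cohort).
#' @param adaptation an [sample_adaptation_set()] object, or a cohort data
#'   frame of adaptation scans.
#' @param batch_vars columns forming the new batches; defaults to the
#'   adaptation set's (`wave` x `sex` for the per-wave configuration,
#'   `scanner` x `sex` for per-scanner).
#' @param control sampler settings; defaults to the reference's.
#' @param freeze_hypers pin hyperparameters at the transfer-prior locations.
#' @param prior_only allow an empty adaptation table (prior-predictive mode).
#' @param new_batches batch keys to create when `prior_only = TRUE`.
#' @return object of class `c("hbr_adapted", "hbr_model")`.
#' @export
hbr_adapt <- function(reference, adaptation, batch_vars = NULL,
                      control = NULL, freeze_hypers = FALSE,
                      prior_only = FALSE, new_batches = NULL) {
  stopifnot(inherits(reference, "hbr_model"))
  if (!all(reference$converged))
    warning("adapting from a reference model with unconverged regions",
            call. = FALSE)
  if (inherits(adaptation, "hbr_adaptation_set")) {
    batch_vars <- batch_vars %||% adaptation$batch_vars
    adat <- adaptation$data
  } else {
    batch_vars <- batch_vars %||% c("wave", "sex")
    adat <- adaptation
  }
  control <- control %||% reference$control
  rois <- reference$roi_names

  if (nrow(adat) == 0) {
    if (!prior_only)
      stop("empty adaptation set; use prior_only = TRUE for the prior-predictive mode",
           call. = FALSE)
    if (is.null(new_batches))
      stop_field("new_batches", "required in prior-only mode")
    batch_keys <- sort(unique(new_batches))
    batch_idx <- integer(0)
    x <- numeric(0)
  } else {
    check_cohort_for_fit(adat, rois, batch_vars)
    key <- make_batch_key(adat, batch_vars)
    batch_keys <- sort(unique(key))
    batch_idx <- match(key, batch_keys)
    x <- standardize_age(adat$age, reference$transform)
  }
  clash <- intersect(batch_keys, reference$batch_keys)
  if (length(clash) > 0)
    stop(sprintf("batch(es) already present in the reference model: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)

  tp <- transfer_priors(hyperposterior_summary(reference))
  roi_fits <- list()
  for (r in rois) {
    y <- if (nrow(adat) == 0) numeric(0) else adat[[paste0("roi_", r)]]
    ctl <- control
    ctl$seed <- derive_seed(control$seed, 500L + match(r, rois))
    roi_fits[[r]] <- fit_hbr_roi(x, y, batch_idx, batch_keys, tp[[r]], ctl,
                                 freeze_hypers = freeze_hypers)
    # combined registry: reference batches first (untouched), then new ones
    ref_reg <- reference$rois[[r]]$batch
    ref_reg$transferred <- FALSE
    new_reg <- roi_fits[[r]]$batch
    new_reg$transferred <- TRUE
    roi_fits[[r]]$batch <- rbind(ref_reg, new_reg)
  }
  conv <- vapply(roi_fits, `[[`, TRUE, "converged")
  if (!all(conv))
    warning(sprintf("adaptation not converged for region(s): %s",
                    paste(names(conv)[!conv], collapse = ", ")), call. = FALSE)
  structure(
    list(rois = roi_fits, roi_names = rois, priors = tp,
         transform = reference$transform, batch_vars = batch_vars,
         batch_keys = batch_keys, reference_batch_keys = reference$batch_keys,
         control = control, freeze_hypers = freeze_hypers, converged = conv,
         n_obs = nrow(adat), reference_hyper = hyperposterior_summary(reference)),
    class = c("hbr_adapted", "hbr_model")
  )
}

#' @export
print.hbr_adapted <- function(x, ...) {
  cat(sprintf("Transferred normative model: %d new %s batch(es) adapted on %d scans\n",
              length(x$batch_keys), paste(x$batch_vars, collapse = " x "),
              x$n_obs))
  cat(sprintf("  hyperpriors informed by a reference model with %d batches\n",
              length(x$reference_batch_keys)))
  cat(sprintf("  hyperparameters %s during adaptation\n",
              if (x$freeze_hypers) "frozen at reference posterior means"
              else "re-sampled under informed priors"))
  cat(sprintf("  converged (split R-hat < 1.05): %d/%d regions\n",
              sum(x$converged), length(x$converged)))
  invisible(x)
}
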