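# Adaptation-size sweep and the validation procedures: within-subject
# stability of deviation scores, the overlapping-age-window comparison, and
# the wave-vs-scanner batch-configuration comparison.

#' Sweep the adaptation-set size
#'
#' For each size in `sizes` and each replicate, samples an adaptation set
#' from a fixed per-batch pool, adapts the reference model, and evaluates it
#' on the common fixed test remainder (the non-withheld scans outside the
#' pool), so every cell of the sweep is scored on identical test rows.
#' Sizes infeasible for the available pool are skipped with a warning and
#' recorded in the result's `skipped` attribute.
#'
#' @param reference fitted reference `hbr_model`.
#' @param target target cohort data frame.
#' @param sizes adaptation sizes (scans per batch) to sweep.
#' @param replicates replicates per size (seeds derived from `seed`).
#' @param strategy sampling strategy, see [sample_adaptation_set()].
#' @param seed master seed.
#' @param batch_vars batch definition for adaptation.
#' @param control sampler settings for the adaptation fits; the default
#'   reduces to one chain of 300 draws after 300 warmup, which is adequate
#'   for these small conjugate-blocked fits and keeps the sweep fast.
#' @param overlap_window validation window withheld from wave 1.
#' @param test_reserve minimum scans per batch kept out of the pool for
#'   testing.
#' @return data frame of class `hbr_sweep`: one row per
#'   (size, replicate, region) with the three metrics; attributes `skipped`
#'   (infeasible sizes) and `n_test`.
#' @seealso [sweep_summary()], [plateau_size()]
#' @export
sweep_adaptation_size <- function(reference, target,
                                  sizes = c(5, 10, 15, 25, 50, 75, 100,
                                            150, 200, 300),
                                  replicates = 10,
                                  strategy = c("random", "age_uniform"),
                                  seed = 1L,
                                  batch_vars = c("wave", "sex"),
                                  control = hbr_control(chains = 1,
                                                        warmup = 300,
                                                        iter = 300),
                                  overlap_window = c(8.6, 10.7),
                                  test_reserve = 50) {
  strategy <- match.arg(strategy)
  sizes <- sort(unique(sizes))
  if (!"row_id" %in% names(target)) target$row_id <- seq_len(nrow(target))
  withheld <- withheld_validation_rows(target, overlap_window)
  clinical <- if ("group" %in% names(target))
    !(target$group %in% "control") else rep(FALSE, nrow(target))
  avail <- target[!withheld & !clinical, , drop = FALSE]
  key <- make_batch_key(avail, batch_vars)
  avail_min <- min(table(key))
  pool_size <- min(max(sizes), avail_min - test_reserve)
  feasible <- sizes[sizes <= pool_size]
  skipped <- setdiff(sizes, feasible)
  if (length(skipped) > 0)
    warning(sprintf("adaptation size(s) infeasible for the available pool (max %d/batch): %s",
                    pool_size, paste(skipped, collapse = ", ")), call. = FALSE)
  if (length(feasible) == 0) stop("no feasible adaptation size", call. = FALSE)

  # fixed per-batch control pool; all other non-withheld scans form the
  # common test set
  set.seed(derive_seed(seed, 71L))
  pool_idx <- draw_batch_sample(avail, pool_size, "random", batch_vars)
  pool <- avail[pool_idx, , drop = FALSE]
  test <- target[!withheld, , drop = FALSE]
  test <- test[!test$row_id %in% pool$row_id, , drop = FALSE]

  out <- list()
  for (s in feasible) {
    for (rep in seq_len(replicates)) {
      rs <- derive_seed(seed, 1000L + 97L * match(s, feasible) + rep)
      set.seed(rs)
      idx <- if (s >= pool_size) seq_len(nrow(pool))
             else draw_batch_sample(pool, s, strategy, batch_vars)
      adat <- pool[idx, , drop = FALSE]
      ctl <- control
      ctl$seed <- rs
      fit <- suppressWarnings(
        hbr_adapt(reference, adat, batch_vars = batch_vars, control = ctl))
      met <- evaluate_model(fit, test, baseline_source = adat)
      met <- met[!met$roi %in% c("(mean)", "(sd)"), ]
      out[[length(out) + 1L]] <- cbind(
        data.frame(size = s, replicate = rep, seed = rs), met)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_test") <- nrow(test)
  class(out) <- c("hbr_sweep", "data.frame")
  out
}

#' Aggregate a sweep across replicates and regions
#'
#' @param sweep an [sweep_adaptation_size()] result.
#' @return data frame: per size, the mean explained variance, SMSE and MSLL
#'   across replicates and regions.
#' @export
sweep_summary <- function(sweep) {
  agg <- stats::aggregate(
    sweep[c("explained_variance", "smse", "msll")],
    by = list(size = sweep$size), FUN = mean)
  agg[order(agg$size), ]
}

#' Plateau and sufficiency sizes of an adaptation sweep
#'
#' `plateau_size()`: the smallest swept size whose mean MSLL is within
#' `tol` nats of the mean at the largest size. `first_negative_msll_size()`:
#' the smallest size at which mean MSLL is negative, i.e. the transferred
#' model beats the trivial training-mean predictor.
#'
#' @param sweep an [sweep_adaptation_size()] result.
#' @param tol plateau tolerance in nats.
#' @return a single size (scans per batch), or `NA` if never reached.
#' @export
plateau_size <- function(sweep, tol = 0.01) {
  agg <- sweep_summary(sweep)
  final <- agg$msll[nrow(agg)]
  ok <- which(agg$msll <= final + tol)
  if (length(ok) == 0) return(NA_integer_)
  agg$size[min(ok)]
}

#' @rdname plateau_size
#' @export
first_negative_msll_size <- function(sweep) {
  agg <- sweep_summary(sweep)
  ok <- which(agg$msll < 0)
  if (length(ok) == 0) return(NA_integer_)
  agg$size[min(ok)]
}

#' Within-subject stability of deviation scores
#'
#' For each subject with at least two waves: the SD of the deviation score
#' across waves per region, and the SD of raw thickness across waves divided
#' by the cross-sectional raw SD of that region. Site-effect-free deviation
#' scores of one subject should sit in a similar range across waves even
#' though raw thickness declines and jumps between scanners.
#'
#' @param dev deviation table from [compute_zscores()].
#' @param raw the matching cohort rows (raw thickness).
#' @return list with `per_subject` (subject-by-region long table) and
#'   `medians` (cohort medians: within-subject z SD, normalized raw SD, and
#'   the cross-sectional z SD for reference). Empty when no subject has
#'   two or more waves.
#' @export
within_subject_stability <- function(dev, raw) {
  nw <- tapply(dev$wave, dev$subject_id, function(w) length(unique(w)))
  keep_ids <- names(nw)[nw >= 2]
  if (length(keep_ids) == 0) {
    warning("no subjects with repeated measurements", call. = FALSE)
    return(list(per_subject = data.frame(), medians = data.frame()))
  }
  rois <- sub("^z_", "", z_cols(dev))
  d <- dev[dev$subject_id %in% keep_ids, , drop = FALSE]
  r <- raw[match(d$row_id, raw$row_id), , drop = FALSE]
  out <- list()
  for (rr in rois) {
    z <- d[[paste0("z_", rr)]]
    y <- r[[paste0("roi_", rr)]]
    cross_sd_raw <- stats::sd(raw[[paste0("roi_", rr)]])
    zs <- tapply(z, d$subject_id, stats::sd)
    ys <- tapply(y, d$subject_id, stats::sd)
    out[[rr]] <- data.frame(
      subject_id = names(zs), roi = rr,
      z_sd = as.numeric(zs),
      raw_sd_norm = as.numeric(ys) / cross_sd_raw,
      stringsAsFactors = FALSE
    )
  }
  per_subject <- do.call(rbind, out)
  rownames(per_subject) <- NULL
  cross_z <- stats::median(vapply(rois, function(rr)
    stats::sd(dev[[paste0("z_", rr)]]), 0))
  medians <- data.frame(
    median_within_z_sd = stats::median(per_subject$z_sd),
    median_raw_sd_norm = stats::median(per_subject$raw_sd_norm),
    cross_sectional_z_sd = cross_z
  )
  list(per_subject = per_subject, medians = medians)
}

pooled_t <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 scans per side", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(v1) + (n2 - 1) * stats::var(v2)) / df
  t <- (mean(v1) - mean(v2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare raw thickness and deviation scores in the overlapping age window
#'
#' Two-sample pooled-variance Student t-tests (df = n1 + n2 - 2) between two
#' batches (typically wave 1 vs wave 2, i.e. the two scanners) restricted to
#' the overlapping age window, on the raw thickness scale and on the
#' deviation-score scale, per region plus a pooled row (the across-region
#' mean per scan). A successful transfer shows a large raw-scale difference
#' and none on the deviation scale.
#'
#' @param raw cohort rows (raw thickness).
#' @param dev the matching deviation table.
#' @param window age window (years).
#' @param batch_a,batch_b levels of `batch_col` to compare.
#' @param batch_col column holding the compared labels (default `"wave"`).
#' @return data frame: `roi`, `scale` (`"raw"`/`"z"`), `t`, `df`, `p`.
#' @export
overlap_range_comparison <- function(raw, dev, window = c(8.6, 10.7),
                                     batch_a, batch_b, batch_col = "wave") {
  sel <- function(df, b) {
    df[df[[batch_col]] == b & df$age >= window[1] & df$age <= window[2], ,
       drop = FALSE]
  }
  ra <- sel(raw, batch_a); rb <- sel(raw, batch_b)
  da <- sel(dev, batch_a); db <- sel(dev, batch_b)
  if (nrow(ra) < 2 || nrow(rb) < 2)
    stop(sprintf("fewer than 2 scans in window for %s or %s", batch_a, batch_b),
         call. = FALSE)
  rois <- sub("^z_", "", z_cols(dev))
  out <- list()
  for (rr in rois) {
    tt <- pooled_t(ra[[paste0("roi_", rr)]], rb[[paste0("roi_", rr)]])
    out[[length(out) + 1L]] <- data.frame(roi = rr, scale = "raw",
                                          t = tt["t"], df = tt["df"], p = tt["p"])
    tt <- pooled_t(da[[paste0("z_", rr)]], db[[paste0("z_", rr)]])
    out[[length(out) + 1L]] <- data.frame(roi = rr, scale = "z",
                                          t = tt["t"], df = tt["df"], p = tt["p"])
  }
  pool_mean <- function(df, cols) rowMeans(as.matrix(df[cols]))
  tt <- pooled_t(pool_mean(ra, paste0("roi_", rois)),
                 pool_mean(rb, paste0("roi_", rois)))
  out[[length(out) + 1L]] <- data.frame(roi = "(pooled)", scale = "raw",
                                        t = tt["t"], df = tt["df"], p = tt["p"])
  tt <- pooled_t(pool_mean(da, paste0("z_", rois)),
                 pool_mean(db, paste0("z_", rois)))
  out[[length(out) + 1L]] <- data.frame(roi = "(pooled)", scale = "z",
                                        t = tt["t"], df = tt["df"], p = tt["p"])
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare per-wave vs per-scanner batch configurations
#'
#' Adapts the reference model twice — once treating each wave as its own
#' batch (`per_wave`), once treating each scanner as one batch
#' (`per_scanner`) — scores the target cohort under each, and reports the
#' per-wave, per-region median deviation score. When waves on a shared
#' scanner differ (e.g. a software upgrade between waves), the per-scanner
#' configuration leaves opposite-signed median offsets in those waves while
#' the per-wave configuration absorbs them.
#'
#' @param reference fitted reference `hbr_model`.
#' @param target target cohort.
#' @param configs which configurations to run.
#' @param n_per_batch adaptation scans per batch.
#' @param seed integer seed.
#' @param control sampler settings for adaptation.
#' @param overlap_window validation window withheld from adaptation.
#' @return data frame: `config`, `wave`, `roi`, `median_z`.
#' @export
batch_config_comparison <- function(reference, target,
                                    configs = c("per_wave", "per_scanner"),
                                    n_per_batch = 100, seed = 1L,
                                    control = hbr_control(chains = 1,
                                                          warmup = 300,
                                                          iter = 300),
                                    overlap_window = c(8.6, 10.7)) {
  out <- list()
  for (cf in configs) {
    bv <- if (cf == "per_wave") c("wave", "sex") else c("scanner", "sex")
    ad <- sample_adaptation_set(target, n_per_batch, strategy = "random",
                                seed = derive_seed(seed, 7L + match(cf, configs)),
                                batch_vars = bv,
                                overlap_window = overlap_window)
    ctl <- control
    ctl$seed <- derive_seed(seed, 17L + match(cf, configs))
    fit <- suppressWarnings(hbr_adapt(reference, ad, control = ctl))
    dev <- compute_zscores(fit, target)
    for (w in sort(unique(dev$wave))) {
      dw <- dev[dev$wave == w & dev$group %in% "control", , drop = FALSE]
      for (rr in sub("^z_", "", z_cols(dev))) {
        out[[length(out) + 1L]] <- data.frame(
          config = cf, wave = w, roi = rr,
          median_z = stats::median(dw[[paste0("z_", rr)]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
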