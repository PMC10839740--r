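# Model evaluation metrics. All variances use population (1/n) moments.

#' Explained variance
#'
#' `1 - Var(y - pred_mean) / Var(y)` with population (1/n), mean-removed
#' variances; 1 for perfect prediction, 0 for any constant predictor.
#'
#' @param y observed values (length >= 2, nonzero variance).
#' @param pred_mean predictive means.
#' @return dimensionless scalar (<= 1), or `NA` with a warning when `Var(y)`
#'   is zero.
#' @export
explained_variance <- function(y, pred_mean) {
  stopifnot(length(y) == length(pred_mean), length(y) >= 2)
  vy <- pop_var(y)
  if (vy == 0) {
    warning("explained variance undefined: zero variance in y", call. = FALSE)
    return(NA_real_)
  }
  1 - pop_var(y - pred_mean) / vy
}

#' Standardized mean squared error
#'
#' `mean((y - pred_mean)^2) / Var(y)` with the population variance of `y`;
#' 0 for perfect prediction, 1 for the trivial mean predictor.
#'
#' @inheritParams explained_variance
#' @export
smse <- function(y, pred_mean) {
  stopifnot(length(y) == length(pred_mean), length(y) >= 2)
  vy <- pop_var(y)
  if (vy == 0) {
    warning("SMSE undefined: zero variance in y", call. = FALSE)
    return(NA_real_)
  }
  mean((y - pred_mean)^2) / vy
}

#' Mean standardized log loss
#'
#' Mean Gaussian negative log predictive density minus that of a trivial
#' Gaussian baseline `N(baseline_mean, baseline_sd^2)` fitted to the
#' model's own training targets for the region; negative values mean the
#' model beats the trivial predictor. In nats.
#'
#' @inheritParams explained_variance
#' @param pred_sd predictive SDs (> 0).
#' @param baseline_mean,baseline_sd trivial-Gaussian baseline parameters,
#'   computed from the adaptation/training targets (never from the test
#'   targets).
#' @export
msll <- function(y, pred_mean, pred_sd, baseline_mean, baseline_sd) {
  stopifnot(length(y) == length(pred_mean), length(y) == length(pred_sd))
  if (any(pred_sd <= 0)) stop_field("pred_sd", "must be > 0")
  if (baseline_sd <= 0) stop_field("baseline_sd", "must be > 0")
  nll_model <- 0.5 * log(2 * pi * pred_sd^2) +
    (y - pred_mean)^2 / (2 * pred_sd^2)
  nll_base <- 0.5 * log(2 * pi * baseline_sd^2) +
    (y - baseline_mean)^2 / (2 * baseline_sd^2)
  mean(nll_model - nll_base)
}

#' Evaluate a normative model on held-out scans
#'
#' Per-region explained variance, SMSE and MSLL over the pooled test rows,
#' with an across-region aggregation row appended. The MSLL baseline
#' Gaussian is fitted (population moments) to the same region's targets in
#' `baseline_source` — the adaptation or training scans — so test statistics
#' never inform the baseline. Row-id overlap between test and baseline rows
#' is rejected as leakage.
#'
#' @param model an `hbr_model` or adapted model.
#' @param test held-out cohort rows.
#' @param baseline_source adaptation/training cohort rows.
#' @param sd_mode predictive SD mode, see [predict.hbr_model()].
#' @return data frame (class `hbr_metrics`): one row per region plus rows
#'   `"(mean)"` and `"(sd)"`; columns `explained_variance`, `smse`, `msll`,
#'   `n_test`.
#' @export
evaluate_model <- function(model, test, baseline_source,
                           sd_mode = c("full", "noise_only")) {
  sd_mode <- match.arg(sd_mode)
  if ("row_id" %in% names(test) && "row_id" %in% names(baseline_source)) {
    ov <- intersect(test$row_id, baseline_source$row_id)
    if (length(ov) > 0)
      stop(sprintf("leakage: %d row(s) present in both test and baseline/adaptation sets",
                   length(ov)), call. = FALSE)
  }
  pr <- predict(model, test, sd_mode = sd_mode)
  rois <- colnames(pr$mean)
  rows <- lapply(rois, function(r) {
    y <- test[[paste0("roi_", r)]]
    yb <- baseline_source[[paste0("roi_", r)]]
    data.frame(
      roi = r,
      explained_variance = explained_variance(y, pr$mean[, r]),
      smse = smse(y, pr$mean[, r]),
      msll = msll(y, pr$mean[, r], pr$sd[, r],
                  baseline_mean = mean(yb), baseline_sd = sqrt(pop_var(yb))),
      n_test = length(y),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  agg <- data.frame(
    roi = c("(mean)", "(sd)"),
    explained_variance = c(mean(out$explained_variance), stats::sd(out$explained_variance)),
    smse = c(mean(out$smse), stats::sd(out$smse)),
    msll = c(mean(out$msll), stats::sd(out$msll)),
    n_test = c(nrow(test), NA),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, agg)
  rownames(out) <- NULL
  class(out) <- c("hbr_metrics", "data.frame")
  out
}

#' Correlate region area with evaluation metrics
#'
#' Pearson correlation (and two-sided p-value) between per-region surface
#' area and each evaluation metric; larger regions have less noisy
#' thickness estimates and are expected to score better.
#'
#' @param report an [evaluate_model()] report (aggregation rows are
#'   dropped).
#' @param areas named per-region areas (names matching `report$roi`), or an
#'   unnamed vector in report order.
#' @return data frame: `metric`, `r`, `p`, `n`; constant metric vectors are
#'   flagged with `NA` and a warning.
#' @export
area_metric_correlation <- function(report, areas) {
  rep0 <- report[!report$roi %in% c("(mean)", "(sd)"), ]
  if (nrow(rep0) < 3) stop("need at least 3 regions", call. = FALSE)
  a <- if (!is.null(names(areas))) areas[rep0$roi] else areas
  if (length(a) != nrow(rep0) || anyNA(a))
    stop_field("areas", "must provide an area for every region in the report")
  out <- list()
  for (m in c("explained_variance", "smse", "msll")) {
    v <- rep0[[m]]
    if (stats::sd(v) == 0 || stats::sd(a) == 0) {
      warning(sprintf("correlation undefined for constant %s", m),
              call. = FALSE)
      out[[m]] <- data.frame(metric = m, r = NA_real_, p = NA_real_,
                             n = length(v), stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(a, v, method = "pearson")
      out[[m]] <- data.frame(metric = m, r = unname(ct$estimate),
                             p = ct$p.value, n = length(v),
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
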