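# Deviation (z) scores and extreme-deviation summaries.

#' Compute per-scan deviation scores
#'
#' Scores every row of `cohort` against a (reference or adapted) normative
#' model: `z = (y - pred_mean) / pred_sd` per region, with the predictive SD
#' taken from [predict.hbr_model()] (full parameter + noise SD by default).
#' The resulting scores are, for a well-adapted model, free of site effects
#' and comparable across scanners and waves.
#'
#' @param model an `hbr_model` or `hbr_adapted` model.
#' @param cohort cohort rows with observed `roi_*` columns; every batch must
#'   be known to the model.
#' @param sd_mode `"full"` or `"noise_only"` predictive SD.
#' @return data frame of covariates plus `z_<roi>`, `mean_<roi>` and
#'   `sd_<roi>` columns (class `hbr_deviation`).
#' @export
compute_zscores <- function(model, cohort, sd_mode = c("full", "noise_only")) {
  sd_mode <- match.arg(sd_mode)
  pr <- predict(model, cohort, sd_mode = sd_mode)
  keep <- intersect(c("row_id", "subject_id", "site", "scanner", "wave",
                      "sex", "age", "group"), names(cohort))
  out <- cohort[keep]
  for (r in colnames(pr$mean)) {
    y <- cohort[[paste0("roi_", r)]]
    if (is.null(y))
      stop(sprintf("cohort lacks observed column roi_%s", r), call. = FALSE)
    out[[paste0("z_", r)]] <- (y - pr$mean[, r]) / pr$sd[, r]
    out[[paste0("mean_", r)]] <- pr$mean[, r]
    out[[paste0("sd_", r)]] <- pr$sd[, r]
  }
  rownames(out) <- NULL
  class(out) <- c("hbr_deviation", "data.frame")
  out
}

z_cols <- function(dev) grep("^z_", names(dev), value = TRUE)

#' Extreme-deviation percentages per region and group
#'
#' Counts, per region and group, the percentage of scans whose deviation
#' score exceeds `+threshold` and falls below `-threshold`.
#'
#' @param dev a deviation table from [compute_zscores()].
#' @param threshold positive deviation threshold (default 2).
#' @param group_col grouping column name (default `"group"`).
#' @return data frame with columns `roi`, `group`, `n`, `pct_above`,
#'   `pct_below` (percent); empty groups are reported with `n = 0` and `NA`
#'   percentages.
#' @export
extreme_deviation_summary <- function(dev, threshold = 2, group_col = "group") {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_field("threshold", "must be > 0")
  if (!group_col %in% names(dev)) stop_field(group_col, "column not found")
  gcol <- dev[[group_col]]
  groups <- if (is.factor(gcol)) levels(gcol) else sort(unique(gcol))
  zc <- z_cols(dev)
  out <- list()
  for (g in groups) {
    sub <- dev[gcol == g, zc, drop = FALSE]
    n <- nrow(sub)
    for (cc in zc) {
      z <- sub[[cc]]
      out[[length(out) + 1L]] <- data.frame(
        roi = sub("^z_", "", cc), group = g, n = n,
        pct_above = if (n > 0) 100 * mean(z > threshold) else NA_real_,
        pct_below = if (n > 0) 100 * mean(z < -threshold) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' Contrast extreme-deviation percentages between two groups
#'
#' Per region and tail, the difference `pct(group_a) - pct(group_b)` in
#' extreme-deviation percentages with a binomial standard error
#' (positive differences mean more extreme deviations in `group_a`). No
#' multiple-testing correction is applied across regions: the output is
#' descriptive, as extreme-deviation maps conventionally are.
#'
#' @param summary output of [extreme_deviation_summary()].
#' @param group_a,group_b group labels to contrast (a minus b).
#' @return long data frame: `roi`, `tail` (`"above"`/`"below"`),
#'   `group_a_pct`, `group_b_pct`, `diff`, `se` (percentage points).
#' @export
group_contrast <- function(summary, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% summary$group)
      stop(sprintf("group not present in summary: %s", g), call. = FALSE)
  }
  a <- summary[summary$group == group_a, ]
  b <- summary[summary$group == group_b, ]
  b <- b[match(a$roi, b$roi), ]
  se_pct <- function(p, n) ifelse(n > 0, sqrt(p * (100 - p) / n), NA_real_)
  out <- list()
  for (tail in c("above", "below")) {
    pa <- a[[paste0("pct_", tail)]]
    pb <- b[[paste0("pct_", tail)]]
    out[[tail]] <- data.frame(
      roi = a$roi, tail = tail, group_a_pct = pa, group_b_pct = pb,
      diff = pa - pb,
      se = sqrt(se_pct(pa, a$n)^2 + se_pct(pb, b$n)^2),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
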