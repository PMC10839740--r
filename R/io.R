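# Cohort CSV and model JSON readers/writers.

COHORT_REQUIRED <- c("subject_id", "site", "sex", "age")

#' Read and write cohort tables
#'
#' Cohorts are wide CSV files: one row per scan with the covariate columns
#' (`subject_id`, `site`, optional `scanner`/`wave`/`group`, `sex`, `age`)
#' and one `roi_<name>` column per region, matching typical per-parcel
#' thickness exports. Reading validates the schema strictly: required
#' columns must exist, thickness must be numeric and complete (scans with
#' missing region data are rejected, naming the offending rows), and a
#' (subject_id, wave) pair may occur at most once.
#'
#' @param path file path.
#' @return `read_cohort()`: the validated cohort data frame (with a
#'   `row_id` column added if absent).
#' @export
read_cohort <- function(path) {
  # read everything as character first: type-guessing would turn a
  # single-sex column ("F") into a logical
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cc in intersect(c("age", "row_id"), names(df)))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if ("row_id" %in% names(df)) df$row_id <- as.integer(df$row_id)
  if ("longitudinal" %in% names(df))
    df$longitudinal <- df$longitudinal == "TRUE"
  for (cc in names(df)) {
    if (is.character(df[[cc]])) df[[cc]][df[[cc]] == "NA"] <- NA
  }
  missing_cols <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("cohort schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  rois <- roi_cols(df)
  if (length(rois) == 0)
    stop("cohort schema error: no roi_* thickness columns", call. = FALSE)
  for (cc in rois) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("cohort schema error: non-numeric or missing thickness in %s at row(s) %s",
                   cc, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    df[[cc]] <- v
  }
  if (!is.numeric(df$age))
    stop("cohort schema error: `age` must be numeric", call. = FALSE)
  if ("wave" %in% names(df)) {
    dup <- duplicated(df[c("subject_id", "wave")])
    if (any(dup))
      stop(sprintf("cohort schema error: duplicate (subject_id, wave) at row(s) %s",
                   paste(utils::head(which(dup), 5), collapse = ", ")),
           call. = FALSE)
  }
  if (!"row_id" %in% names(df)) df$row_id <- seq_len(nrow(df))
  df
}

#' @rdname read_cohort
#' @param cohort cohort data frame to write.
#' @return `write_cohort()`: the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @param config an [cohort_config()] (written as JSON alongside cohorts).
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "hbr_cohort_config"))
  obj <- unclass(config)
  if (!is.null(obj$scanner_offsets)) {
    obj$scanner_offsets <- list(scanner = names(obj$scanner_offsets),
                                offset = unname(obj$scanner_offsets))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$target_waves <- as.data.frame(raw$target_waves,
                                    stringsAsFactors = FALSE)
  if (!is.null(raw$scanner_offsets))
    raw$scanner_offsets <- stats::setNames(raw$scanner_offsets$offset,
                                           raw$scanner_offsets$scanner)
  do.call(cohort_config, raw)
}

MODEL_FORMAT_VERSION <- "1"

#' Save and load fitted models as JSON
#'
#' Serializes the summaries a model needs for prediction and transfer — the
#' age transform, batch registry (per-batch posterior means, covariances and
#' noise variances), hyperparameter posterior summaries and convergence
#' diagnostics — at full numeric precision, one block per region. Raw MCMC
#' draws are not stored; a reloaded model reproduces [predict.hbr_model()]
#' and [transfer_priors()] outputs bit-identically. A version field guards
#' against format drift.
#'
#' @param model an `hbr_model` or `hbr_adapted` model.
#' @param path file path (JSON).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hbr_model"))
  rois <- lapply(model$roi_names, function(r) {
    f <- model$rois[[r]]
    list(batch = f$batch, hyper = f$hyper,
         rhat = as.list(f$rhat), converged = f$converged)
  })
  names(rois) <- model$roi_names
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    class = class(model),
    transform = unclass(model$transform),
    batch_vars = model$batch_vars,
    batch_keys = model$batch_keys,
    reference_batch_keys = model$reference_batch_keys,
    freeze_hypers = model$freeze_hypers,
    n_obs = model$n_obs,
    converged = as.list(model$converged),
    control = unclass(model$control),
    rois = rois
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()`: the reconstructed model object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("cannot parse model file %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (is.null(obj$format_version) ||
      !identical(as.character(obj$format_version), MODEL_FORMAT_VERSION))
    stop(sprintf("model format version mismatch: file has %s, package reads %s",
                 obj$format_version %||% "<none>", MODEL_FORMAT_VERSION),
         call. = FALSE)
  roi_names <- names(obj$rois)
  roi_fits <- lapply(obj$rois, function(blk) {
    list(
      batch = as.data.frame(blk$batch, stringsAsFactors = FALSE),
      hyper = as.data.frame(blk$hyper, stringsAsFactors = FALSE),
      rhat = unlist(blk$rhat),
      converged = isTRUE(blk$converged),
      draws = NULL
    )
  })
  model <- list(
    rois = roi_fits, roi_names = roi_names,
    transform = structure(obj$transform, class = "hbr_age_transform"),
    batch_vars = obj$batch_vars, batch_keys = obj$batch_keys,
    reference_batch_keys = obj$reference_batch_keys,
    control = obj$control, freeze_hypers = obj$freeze_hypers %||% FALSE,
    converged = unlist(obj$converged), n_obs = obj$n_obs
  )
  class(model) <- obj$class
  model
}
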