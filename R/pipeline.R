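# End-to-end orchestration: normalize -> cutoffs -> stratify -> survival ->
# immune, with a nested key-value configuration, machine-parsable logging,
# and a deterministic machine-readable report. The pipeline itself draws no
# random numbers: identical inputs and configuration reproduce the report
# byte for byte.

#' Default pipeline configuration
#'
#' Nested list of stage settings. Any subset can be overridden by passing
#' named lists; unrecognized keys are an error. The cutoff stage either
#' derives thresholds from the data ([derive_her2_cutoffs()]) or applies
#' supplied ones (set both `cutoffs$cut_ultralow` and
#' `cutoffs$cut_positive`, reproducing the transfer of calibration-cohort
#' cutoffs to a larger database); the report records which path was taken.
#'
#' @param ... Named stage overrides, e.g.
#'   `normalization = list(enabled = FALSE)`.
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    normalization = list(enabled = TRUE, target_mean = 1000,
                         assume_summarized = TRUE),
    cutoffs = list(enabled = TRUE, criterion = "youden", spec_level = 0.90,
                   cut_ultralow = NULL, cut_positive = NULL),
    stratify = list(her2_probe = "216836_s_at", esr1_probe = "205225_at",
                    esr1_cutoff = 500),
    survival = list(enabled = TRUE, endpoints = c("rfs", "dmfs", "os"),
                    strata = c("hr_positive", "hr_negative")),
    immune = list(enabled = TRUE, p_threshold = 0.01, auc_threshold = 0.6)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) stop("unknown configuration section: ", nm)
    bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
    if (length(bad)) stop("unknown key in section ", nm, ": ",
                          paste(bad, collapse = ", "))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]],
                                        keep.null = TRUE)
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the sections of
#'   [pipeline_config()].
#' @return A `pipeline_config` with file values layered over the defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(pipeline_config, cfg)
}

#' Run the full stratification pipeline
#'
#' Executes, in fixed order, sample normalization, HER2 cutoff derivation
#' (or application of supplied cutoffs), six-subgroup stratification,
#' survival comparisons per endpoint and HR stratum, and immune signature
#' activation scoring with pairwise subgroup overlap. Stages can be disabled
#' in the configuration; a disabled or inapplicable stage is marked
#' `skipped` in the report, a failing stage is marked `error` with its
#' message, and later stages that depend on it are skipped. Warnings and
#' sample-accounting messages are captured into the report log.
#'
#' @param expression Probe-by-sample matrix (see
#'   [read_expression_matrix()]).
#' @param clinical Clinical table (see [read_clinical_table()]).
#' @param signatures Optional named list of gene sets (see [read_gmt()]);
#'   without it the immune stage is skipped.
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`; inspect with `print()`, persist
#'   with [write_report()]. `report$ok` is `FALSE` when any enabled stage
#'   errored.
#' @export
run_pipeline <- function(expression, clinical, signatures = NULL,
                         config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  report <- list(config = unclass(config),
                 stages = list(),
                 log = character(),
                 versions = list(
                   her2strat = as.character(utils::packageVersion("her2strat")),
                   r = paste(R.version$major, R.version$minor, sep = ".")))
  log_line <- function(...) {
    report$log <<- c(report$log, paste0(...))
  }
  run_stage <- function(name, enabled, fn) {
    if (!enabled) {
      report$stages[[name]] <<- list(status = "skipped")
      log_line("stage ", name, ": skipped")
      return(NULL)
    }
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        report$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
        log_line("stage ", name, ": ERROR ", conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        log_line("stage ", name, ": warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        log_line("stage ", name, ": ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    if (!is.null(res)) {
      report$stages[[name]] <<- list(status = "ok")
      log_line("stage ", name, ": ok")
    }
    res
  }

  # normalize
  normalized <- run_stage("normalize", isTRUE(config$normalization$enabled),
                          function()
                            scale_samples_to_mean(
                              expression, config$normalization$target_mean))
  if (is.null(normalized)) {
    if (identical(report$stages$normalize$status, "error")) {
      report$ok <- FALSE
      return(structure(report, class = "run_report"))
    }
    normalized <- expression
  }

  # cutoffs: derived from IHC/FISH labels, or supplied in configuration
  ccfg <- config$cutoffs
  supplied <- !is.null(ccfg$cut_ultralow) && !is.null(ccfg$cut_positive)
  cuts <- NULL
  if (supplied || !isTRUE(ccfg$enabled)) {
    cuts <- if (supplied)
      her2_cutoffs(ccfg$cut_ultralow, ccfg$cut_positive) else her2_cutoffs()
    report$stages[["cutoffs"]] <- list(status = if (supplied) "ok" else "skipped")
    report$cutoffs <- list(path = if (supplied) "supplied" else "default",
                           cut_ultralow = cuts$cut_ultralow,
                           cut_positive = cuts$cut_positive)
    log_line("stage cutoffs: ", report$cutoffs$path, " thresholds ",
             cuts$cut_ultralow, " / ", cuts$cut_positive)
  } else {
    derived <- run_stage("cutoffs", TRUE, function()
      derive_her2_cutoffs(normalized, clinical,
                          her2_probe = config$stratify$her2_probe,
                          criterion = ccfg$criterion,
                          spec_level = ccfg$spec_level))
    if (!is.null(derived)) {
      cuts <- derived$cuts
      report$cutoffs <- list(path = "derived",
                             cut_ultralow = cuts$cut_ultralow,
                             cut_positive = cuts$cut_positive,
                             detail = list(
                               cut_positive = unclass(derived$cut_positive),
                               cut_ultralow = unclass(derived$cut_ultralow)))
    }
  }
  if (is.null(cuts)) {
    report$ok <- FALSE
    return(structure(report, class = "run_report"))
  }

  # stratify
  scfg <- config$stratify
  assignments <- run_stage("stratify", TRUE, function()
    assign_subgroups(normalized, clinical,
                     her2_probe = scfg$her2_probe,
                     esr1_probe = scfg$esr1_probe,
                     cuts = cuts, esr1_cutoff = scfg$esr1_cutoff))
  if (is.null(assignments)) {
    report$ok <- FALSE
    return(structure(report, class = "run_report"))
  }
  n_excluded <- length(attr(assignments, "excluded_her2_zero"))
  n_unmatched <- length(attr(assignments, "unmatched"))
  report$accounting <- list(
    samples_in = length(union(colnames(expression), clinical$sample_id)),
    samples_assigned = nrow(assignments),
    samples_excluded_her2_zero = n_excluded,
    samples_unmatched = n_unmatched)
  report$distribution <- subgroup_distribution(assignments)

  # survival
  vcfg <- config$survival
  surv <- run_stage("survival", isTRUE(vcfg$enabled), function() {
    out <- list()
    for (ep in vcfg$endpoints) for (st in vcfg$strata) {
      cmp <- compare_subgroup_survival(assignments, clinical, ep, st)
      out[[paste(ep, st, sep = ".")]] <- cmp
    }
    out
  })
  if (!is.null(surv)) report$survival <- surv

  # immune
  icfg <- config$immune
  immune <- run_stage("immune",
                      isTRUE(icfg$enabled) && !is.null(signatures),
                      function() {
    act <- signature_activation_matrix(normalized, assignments, signatures,
                                       icfg$p_threshold, icfg$auc_threshold)
    list(activation = act,
         overlap = list(min_set = overlap_matrix(act, "min_set"),
                        jaccard = overlap_matrix(act, "jaccard")))
  })
  if (!is.null(immune)) report$immune <- immune

  statuses <- vapply(report$stages, `[[`, character(1L), "status")
  report$ok <- !any(statuses == "error")
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", if (isTRUE(x$ok)) "ok" else "FAILED", "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$cutoffs))
    cat(sprintf("  cutoffs (%s): ultralow < %.6g, positive >= %.6g\n",
                x$cutoffs$path, x$cutoffs$cut_ultralow,
                x$cutoffs$cut_positive))
  if (!is.null(x$distribution)) {
    cat("  subgroup distribution:\n")
    d <- x$distribution
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-18s %5d  %5.1f%%\n", d$label[i], d$count[i],
                  100 * d$fraction[i]))
  }
  invisible(x)
}

# Strip classes and reduce matrices/data frames to plain JSON-able lists.
.jsonable <- function(x) {
  if (inherits(x, "km_curve")) return(lapply(unclass(x), unname))
  if (is.matrix(x))
    return(list(rows = rownames(x), cols = colnames(x),
                values = apply(unname(x), 1L, as.numeric, simplify = FALSE)))
  if (is.data.frame(x)) return(lapply(as.list(x), unname))
  if (is.list(x)) return(lapply(unclass(x), .jsonable))
  x
}

#' Write a run report as JSON
#'
#' Deterministic serialization (no timestamps): reruns with identical
#' inputs, configuration and seed produce byte-identical files.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(.jsonable(unclass(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
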