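#' Pipeline configuration
#'
#' Assembles and validates the options for [run_pipeline()]. Inputs may be
#' in-memory objects or file paths (CSV for responses and grids, JSON/YAML
#' for the hierarchy).
#'
#' @param responses Kano responses: data frame or CSV path.
#' @param hierarchy AHP hierarchy: [ahp_hierarchy()] or JSON/YAML path.
#' @param feature_map Need-to-feature map: data frame or CSV path.
#' @param hoq_grid Symbol grid: character matrix or CSV path.
#' @param absolute_weights Optional named vector of absolute technical
#'   weights; when supplied, the QFD stage normalizes and ranks these
#'   instead of computing them from the grid.
#' @param stages Which stages to run, in order, a subset of
#'   `c("kano", "ahp", "qfd")`.
#' @param tie_break,exclude,q_warn Kano options, see [kano_summary()].
#' @param weight_method,ri_table,cr_threshold,force AHP options, see
#'   [ahp_synthesize()].
#' @param scale QFD symbol scale, see [symbol_scale()].
#' @param seed Optional integer seed (the stages themselves are
#'   deterministic; the seed is recorded for provenance and used by any
#'   simulation inputs).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(responses = NULL, hierarchy = NULL,
                            feature_map = NULL, hoq_grid = NULL,
                            absolute_weights = NULL,
                            stages = c("kano", "ahp", "qfd"),
                            tie_break = c("M", "O", "A", "I", "R", "Q"),
                            exclude = "R", q_warn = 0.1,
                            weight_method = "eigenvector", ri_table = NULL,
                            cr_threshold = 0.1, force = FALSE,
                            scale = symbol_scale(), seed = NULL) {
  stages <- match.arg(stages, c("kano", "ahp", "qfd"), several.ok = TRUE)
  structure(
    list(responses = responses, hierarchy = hierarchy,
         feature_map = feature_map, hoq_grid = hoq_grid,
         absolute_weights = absolute_weights, stages = stages,
         tie_break = tie_break, exclude = exclude, q_warn = q_warn,
         weight_method = weight_method, ri_table = ri_table,
         cr_threshold = cr_threshold, force = force, scale = scale,
         seed = seed),
    class = "pipeline_config"
  )
}

pipeline_error <- function(stage, message, report) {
  stop(errorCondition(
    paste0("pipeline stage '", stage, "' failed: ", message),
    class = c("kanoqfd_pipeline_error", "error", "condition"),
    stage = stage, report = report))
}

#' Run the requirement-prioritization pipeline
#'
#' Executes the configured stages in order: Kano summary and filtering of
#' the requirement set, AHP synthesis of comprehensive weights, and QFD
#' translation into ranked technical-feature weights. All numeric results
#' are deterministic given the configuration; warnings raised inside the
#' stages are collected into the report. A failing stage aborts with a
#' condition of class `"kanoqfd_pipeline_error"` carrying the stage name
#' and the partial report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"run_report"`: `stages` (per-stage outputs),
#'   `warnings`, and `provenance` (seed, timestamp, package version and the
#'   effective options).
#' @export
#' @examples
#' study <- scooter_study()
#' rep <- run_pipeline(pipeline_config(
#'   responses = study$responses, hierarchy = study$hierarchy,
#'   feature_map = study$feature_map,
#'   absolute_weights = setNames(study$technical_weights$absolute_weight,
#'                               study$technical_weights$feature)))
#' rep$stages$qfd$feature[rep$stages$qfd$rank == 1]
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings[[length(warnings) + 1L]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }
  out <- list()
  report <- function() {
    structure(
      list(stages = out, warnings = warnings,
           provenance = list(
             seed = config$seed,
             timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
             package_version = as.character(packageVersion("kanoqfd")),
             options = config[c("stages", "exclude", "weight_method",
                                "cr_threshold", "force")])),
      class = "run_report")
  }

  if ("kano" %in% config$stages) {
    out$kano <- tryCatch(collect({
      resp <- config$responses
      if (is.character(resp)) resp <- read_kano_csv(resp)
      if (is.null(resp)) stop("no Kano responses configured")
      kano_summary(resp, tie_break = config$tie_break,
                   exclude = config$exclude, q_warn = config$q_warn)
    }), error = function(e) pipeline_error("kano", conditionMessage(e), report()))
  }

  if ("ahp" %in% config$stages) {
    out$ahp <- tryCatch(collect({
      hier <- config$hierarchy
      if (is.character(hier)) hier <- read_hierarchy(hier)
      if (is.null(hier)) stop("no AHP hierarchy configured")
      if (!is.null(out$kano)) {
        inds <- unlist(lapply(hier$indicators, rownames), use.names = FALSE)
        dropped <- intersect(inds,
                             out$kano$requirement_id[!out$kano$retained])
        if (length(dropped)) {
          warning("hierarchy contains requirement(s) the Kano filter dropped: ",
                  paste(dropped, collapse = ", "), call. = FALSE)
        }
      }
      ahp_synthesize(hier, method = config$weight_method,
                     ri_table = config$ri_table,
                     threshold = config$cr_threshold, force = config$force)
    }), error = function(e) pipeline_error("ahp", conditionMessage(e), report()))
  }

  if ("qfd" %in% config$stages) {
    out$qfd <- tryCatch(collect({
      if (!is.null(config$absolute_weights)) {
        hoq_report(config$absolute_weights)
      } else {
        fm <- config$feature_map
        if (is.character(fm)) {
          fm <- read.csv(fm, stringsAsFactors = FALSE, encoding = "UTF-8")
        }
        grid <- config$hoq_grid
        if (is.character(grid) && length(grid) == 1L && file.exists(grid)) {
          grid <- read_hoq_grid(grid)
        }
        if (is.null(out$ahp)) stop("QFD from a grid needs the AHP stage")
        if (is.null(fm) || is.null(grid)) {
          stop("QFD stage needs feature_map and hoq_grid (or absolute_weights)")
        }
        build_hoq_report(out$ahp, fm, grid, scale = config$scale)$report
      }
    }), error = function(e) pipeline_error("qfd", conditionMessage(e), report()))
  }

  report()
}

#' @export
print.run_report <- function(x, ...) {
  cat("kanoqfd run (", x$provenance$timestamp, ", v",
      x$provenance$package_version, ")\n", sep = "")
  for (st in names(x$stages)) {
    cat("-- stage: ", st, "\n", sep = "")
    print(x$stages[[st]])
  }
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}
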