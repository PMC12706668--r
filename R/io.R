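#' Read a Kano questionnaire CSV
#'
#' Long-format file with columns `respondent_id`, `requirement_id`,
#' `functional`, `dysfunctional`; answers are integers 1--5 or canonical
#' scale labels. Malformed answers are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Data frame ready for [kano_summary()].
#' @export
read_kano_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("respondent_id", "requirement_id", "functional", "dysfunctional")
  if (!all(need %in% names(x))) {
    stop("Kano CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("no data rows in ", path, call. = FALSE)
  for (col in c("functional", "dysfunctional")) {
    x[[col]] <- tryCatch(as_kano_answer(x[[col]]), error = function(e) {
      raw <- x[[col]]
      parsed <- suppressWarnings(vapply(raw, function(v) {
        tryCatch(as_kano_answer(v), error = function(e) NA_integer_)
      }, integer(1)))
      bad <- which(is.na(parsed) & !is.na(raw))
      stop("invalid ", col, " answer(s) in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    })
  }
  x
}

#' Write Kano responses or a Kano summary to CSV
#'
#' Values round-trip through [read_kano_csv()] / `read.csv` unchanged.
#' Fractions are stored as fractions; percent strings belong to reports
#' only.
#'
#' @param x Data frame (responses or a [kano_summary()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kano_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an AHP hierarchy from JSON or YAML
#'
#' Expected structure: a `goal` string, a `criteria` object with `labels`
#' and a square `matrix`, and an `indicators` object mapping every criterion
#' label to its own `labels` and `matrix`. Matrices may be full or
#' upper-triangular (lower entries `null`/`NA`, filled by reciprocals).
#' An optional top-level `reciprocity_tol` loosens the reciprocity check
#' for matrices transcribed at limited decimal precision.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return An [ahp_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  }
  for (field in c("goal", "criteria", "indicators")) {
    if (is.null(cfg[[field]])) {
      stop("hierarchy file missing field: ", field, call. = FALSE)
    }
  }
  tol <- if (is.null(cfg$reciprocity_tol)) 1e-6 else cfg$reciprocity_tol
  as_mat <- function(node, what) {
    m <- node$matrix
    if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
    m <- as.matrix(m)
    labels <- unlist(node$labels)
    if (length(labels) != nrow(m)) {
      stop("labels and matrix size disagree for ", what, call. = FALSE)
    }
    pairwise_matrix(m, labels = labels, tol = tol)
  }
  criteria <- as_mat(cfg$criteria, "criteria")
  ind_names <- names(cfg$indicators)
  missing <- setdiff(rownames(criteria), ind_names)
  if (length(missing)) {
    stop("criterion without an indicator matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  indicators <- lapply(setNames(nm = rownames(criteria)), function(cr) {
    as_mat(cfg$indicators[[cr]], paste("indicators of", cr))
  })
  ahp_hierarchy(cfg$goal, criteria, indicators)
}

#' Read a House of Quality symbol grid from CSV
#'
#' First column holds the need ids, remaining columns one technical feature
#' each; cells are relationship symbols (or ASCII aliases, or blank).
#'
#' @param path CSV file path (UTF-8).
#' @return Character matrix with need row names and feature column names.
#' @export
read_hoq_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                encoding = "UTF-8", colClasses = "character")
  if (ncol(x) < 2L) stop("HOQ grid needs a need column plus features", call. = FALSE)
  g <- as.matrix(x[, -1, drop = FALSE])
  rownames(g) <- x[[1]]
  g
}

#' Write an AHP weight table or HOQ report
#'
#' @param x A data frame (e.g. from [ahp_synthesize()] or [hoq_report()]).
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, digits = NA, pretty = TRUE)
  } else {
    write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
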