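#' The five-level Kano answer scale
#'
#' Paired Kano questions are answered on a five-point scale. Both numeric
#' codes (1--5) and the canonical labels are accepted throughout the package.
#'
#' @return A named integer vector mapping labels to codes:
#'   Dislike = 1, Live-with = 2, Neutral = 3, Must-be = 4, Like = 5.
#' @export
#' @examples
#' kano_answer_scale()
kano_answer_scale <- function() {
  c(Dislike = 1L, `Live-with` = 2L, Neutral = 3L, `Must-be` = 4L, Like = 5L)
}

#' The six Kano categories
#'
#' Attractive (A), One-dimensional (O), Must-be (M), Indifferent (I),
#' Reverse (R) and Questionable (Q); exhaustive and mutually exclusive.
#'
#' @return Character vector of the six category codes.
#' @export
kano_categories <- function() c("A", "O", "M", "I", "R", "Q")

# Coerce answers given as integers 1..5 or canonical labels (case- and
# punctuation-insensitive) to integer codes; anything else is a scale error.
as_kano_answer <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    key <- gsub("[^a-z]", "", tolower(x))
    scale <- kano_answer_scale()
    names(scale) <- gsub("[^a-z]", "", tolower(names(scale)))
    # numeric strings pass through
    num <- suppressWarnings(as.integer(x))
    out <- ifelse(is.na(num), unname(scale[key]), num)
  } else {
    if (any(!is.na(x) & x != round(x))) {
      stop("Kano answers must be integers 1-5 or scale labels", call. = FALSE)
    }
    out <- as.integer(x)
  }
  bad <- !is.na(x) & (is.na(out) | out < 1L | out > 5L)
  if (any(bad)) {
    stop("invalid Kano answer(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected 1-5 or Dislike/Live-with/Neutral/Must-be/Like)",
         call. = FALSE)
  }
  out
}

#' Kano evaluation table
#'
#' The 5 x 5 lookup mapping a (functional, dysfunctional) answer pair to a
#' Kano category. Rows index the functional (presence) answer, columns the
#' dysfunctional (absence) answer, both on the scale of
#' [kano_answer_scale()]. The default is the standard evaluation table:
#' the (Like, Dislike) cell is One-dimensional, (Like, x) cells for middling
#' x are Attractive, (x, Dislike) cells are Must-be, agreement on the
#' diagonal extremes is Questionable, and reversed preferences are Reverse.
#'
#' @param cells Optional 5 x 5 character matrix of category codes overriding
#'   the default (rows = functional answer 1..5, columns = dysfunctional
#'   answer 1..5).
#' @return A 5 x 5 character matrix of class `"kano_evaluation_table"`.
#' @export
#' @examples
#' tab <- kano_evaluation_table()
#' tab["Like", "Dislike"]   # "O"
kano_evaluation_table <- function(cells = NULL) {
  labs <- names(kano_answer_scale())
  if (is.null(cells)) {
    cells <- rbind(
      c("Q", "R", "R", "R", "R"),  # functional = Dislike
      c("M", "I", "I", "I", "R"),  # functional = Live-with
      c("M", "I", "I", "I", "R"),  # functional = Neutral
      c("M", "I", "I", "I", "R"),  # functional = Must-be
      c("O", "A", "A", "A", "Q")   # functional = Like
    )
  }
  cells <- as.matrix(cells)
  if (!identical(dim(cells), c(5L, 5L))) {
    stop("evaluation table must be 5 x 5", call. = FALSE)
  }
  if (!all(cells %in% kano_categories())) {
    stop("evaluation table cells must be one of ",
         paste(kano_categories(), collapse = ", "), call. = FALSE)
  }
  dimnames(cells) <- list(functional = labs, dysfunctional = labs)
  class(cells) <- c("kano_evaluation_table", class(cells))
  cells
}

#' Classify paired Kano answers
#'
#' Pure lookup of the (functional, dysfunctional) answer pair in the
#' evaluation table; total over all 25 pairs. Vectorized.
#'
#' @param functional,dysfunctional Answers on the five-level scale (integer
#'   codes or labels); recycled to a common length.
#' @param table A [kano_evaluation_table()].
#' @return Character vector of category codes.
#' @export
#' @examples
#' kano_classify("Like", "Dislike")      # "O"
#' kano_classify(4, 1)                   # "M"
kano_classify <- function(functional, dysfunctional,
                          table = kano_evaluation_table()) {
  f <- as_kano_answer(functional)
  d <- as_kano_answer(dysfunctional)
  if (anyNA(f) || anyNA(d)) {
    stop("missing Kano answers cannot be classified", call. = FALSE)
  }
  unname(table[cbind(f, d)])
}

#' Tabulate Kano responses for one requirement
#'
#' Classifies every response of a single requirement and counts categories.
#'
#' @param responses Data frame with columns `respondent_id`,
#'   `requirement_id`, `functional`, `dysfunctional`, all rows for the same
#'   requirement. Rows with a missing answer on either side are dropped with
#'   a warning (an incomplete pair contributes nothing).
#' @param table A [kano_evaluation_table()].
#' @return A list of class `"kano_stats"` with elements `requirement_id`,
#'   `n` (respondents counted), `counts` and `fractions` (named over the six
#'   categories; fractions sum to 1).
#' @export
kano_tabulate <- function(responses, table = kano_evaluation_table()) {
  stopifnot(is.data.frame(responses))
  req <- unique(as.character(responses$requirement_id))
  if (length(req) == 0L || nrow(responses) == 0L) {
    stop("no responses supplied", call. = FALSE)
  }
  if (length(req) > 1L) {
    stop("responses mix requirement ids: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.na(req) || !nzchar(req)) {
    stop("requirement_id must be non-empty", call. = FALSE)
  }
  incomplete <- is.na(responses$functional) | is.na(responses$dysfunctional)
  if (any(incomplete)) {
    warning(sum(incomplete), " incomplete answer pair(s) dropped for ",
            req, call. = FALSE)
    responses <- responses[!incomplete, , drop = FALSE]
  }
  if (nrow(responses) == 0L) {
    stop("no complete answer pairs for ", req, call. = FALSE)
  }
  cats <- kano_classify(responses$functional, responses$dysfunctional, table)
  counts <- vapply(kano_categories(), function(k) sum(cats == k), integer(1))
  structure(
    list(requirement_id = req, n = nrow(responses), counts = counts,
         fractions = counts / sum(counts)),
    class = "kano_stats"
  )
}

#' @export
print.kano_stats <- function(x, ...) {
  cat("Kano stats for ", x$requirement_id, " (n = ", x$n, ")\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Modal Kano category with deterministic tie-break
#'
#' Returns the most frequent category; ties are resolved by a priority
#' ordering, by default M > O > A > I > R > Q (safety-critical categories
#' first).
#'
#' @param stats A `"kano_stats"` object or a named count/fraction vector
#'   over the six categories.
#' @param tie_break Character vector giving the priority ordering used to
#'   break frequency ties.
#' @return A single category code.
#' @export
#' @examples
#' kano_modal_category(c(A = 2, O = 0, M = 2, I = 0, R = 0, Q = 0))  # "M"
kano_modal_category <- function(stats,
                                tie_break = c("M", "O", "A", "I", "R", "Q")) {
  counts <- if (inherits(stats, "kano_stats")) stats$counts else stats
  if (!setequal(names(counts), kano_categories())) {
    stop("counts must be named over the six Kano categories", call. = FALSE)
  }
  if (!setequal(tie_break, kano_categories())) {
    stop("tie_break must order all six Kano categories", call. = FALSE)
  }
  counts <- counts[tie_break]  # stable order: ties fall to earlier priority
  names(counts)[which.max(counts)]
}

#' Better-Worse coefficients (SI and DSI)
#'
#' The satisfaction index `SI = (A + O) / (A + O + M + I)` and the
#' dissatisfaction index `DSI = -(O + M) / (A + O + M + I)`. Reverse and
#' Questionable responses are excluded from the denominator; their fractions
#' are still reported elsewhere. SI lies in \[0, 1\], DSI in \[-1, 0\]; an SI
#' near 1 marks a requirement whose fulfilment raises satisfaction, a DSI
#' near -1 one whose absence depresses it.
#'
#' @param stats A `"kano_stats"` object or named count/fraction vector.
#' @return Named numeric vector `c(SI = , DSI = )`.
#' @export
#' @examples
#' kano_better_worse(c(A = 8, O = 18, M = 2, I = 4, R = 0, Q = 0))
kano_better_worse <- function(stats) {
  x <- if (inherits(stats, "kano_stats")) stats$counts else stats
  if (!setequal(names(x), kano_categories())) {
    stop("counts must be named over the six Kano categories", call. = FALSE)
  }
  denom <- x[["A"]] + x[["O"]] + x[["M"]] + x[["I"]]
  if (denom <= 0) {
    stop("degenerate requirement: all responses Reverse/Questionable, ",
         "Better-Worse coefficients undefined", call. = FALSE)
  }
  c(SI = (x[["A"]] + x[["O"]]) / denom,
    DSI = -(x[["O"]] + x[["M"]]) / denom)
}

#' Summarize a full Kano questionnaire
#'
#' Tabulates every requirement, assigns modal categories, computes
#' Better-Worse coefficients and flags the requirements retained for
#' downstream weighting (those not classified into the exclusion set).
#' Requirements whose responses are all Reverse/Questionable get `NA`
#' coefficients and are flagged, never silently dropped. A data-quality
#' warning is emitted when a requirement's Questionable fraction exceeds
#' `q_warn` (commonly a sign of confusing question wording).
#'
#' @param responses Long-format data frame with columns `respondent_id`,
#'   `requirement_id`, `functional`, `dysfunctional`.
#' @param table A [kano_evaluation_table()].
#' @param tie_break Priority ordering passed to [kano_modal_category()].
#' @param exclude Categories whose requirements are dropped from the retained
#'   list (default `"R"`; use `c("R", "I")` to also drop Indifferent).
#' @param q_warn Questionable-fraction threshold for the data-quality warning.
#' @return A data frame of class `"kano_summary"` with one row per
#'   requirement: `requirement_id`, `n`, the six category fractions,
#'   `category`, `SI`, `DSI`, Better-Worse scatter coordinates
#'   `bw_x` (= |DSI|) and `bw_y` (= SI), and logical `retained`.
#'   Per-category counts are attached as `attr(, "counts")`.
#' @export
kano_summary <- function(responses, table = kano_evaluation_table(),
                         tie_break = c("M", "O", "A", "I", "R", "Q"),
                         exclude = "R", q_warn = 0.1) {
  stopifnot(is.data.frame(responses))
  if (!all(exclude %in% kano_categories())) {
    stop("exclude must be a subset of the six Kano categories", call. = FALSE)
  }
  ids <- unique(as.character(responses$requirement_id))
  if (length(ids) == 0L) stop("no responses supplied", call. = FALSE)
  stats <- lapply(ids, function(id) {
    kano_tabulate(responses[responses$requirement_id == id, , drop = FALSE],
                  table)
  })
  counts <- t(vapply(stats, function(s) s$counts, numeric(6)))
  fr <- counts / rowSums(counts)
  category <- vapply(stats, kano_modal_category, character(1),
                     tie_break = tie_break)
  bw <- t(vapply(stats, function(s) {
    denom <- sum(s$counts[c("A", "O", "M", "I")])
    if (denom == 0) c(SI = NA_real_, DSI = NA_real_) else kano_better_worse(s)
  }, numeric(2)))
  high_q <- fr[, "Q"] > q_warn
  if (any(high_q)) {
    warning("Questionable fraction exceeds ", q_warn, " for: ",
            paste(ids[high_q], collapse = ", "),
            " - check questionnaire wording", call. = FALSE)
  }
  out <- data.frame(
    requirement_id = ids, n = vapply(stats, `[[`, numeric(1), "n"),
    fr, category = category,
    SI = bw[, "SI"], DSI = bw[, "DSI"],
    bw_x = abs(bw[, "DSI"]), bw_y = bw[, "SI"],
    retained = !(category %in% exclude),
    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(counts) <- ids
  attr(out, "counts") <- counts
  class(out) <- c("kano_summary", class(out))
  out
}

#' @export
print.kano_summary <- function(x, digits = 4, ...) {
  cat("Kano summary: ", nrow(x), " requirements, ",
      sum(x$retained), " retained\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Requirements retained after Kano filtering
#'
#' @param x A `"kano_summary"`.
#' @return Character vector of retained requirement ids.
#' @export
retained_requirements <- function(x) {
  stopifnot(inherits(x, "kano_summary"))
  x$requirement_id[x$retained]
}
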