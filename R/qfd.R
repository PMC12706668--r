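#' Relationship-strength symbol scale
#'
#' The House of Quality marks need-feature relationships with filled circle
#' (strong), double circle (moderate) and triangle (weak) symbols; blank
#' cells mean no relationship. ASCII aliases `S`, `M`, `W` are accepted
#' alongside the symbols for portability. The default strengths are
#' 5 / 3 / 1; a 9 / 3 / 1 dialect is a matter of passing different values.
#'
#' @param strong,moderate,weak Non-negative numeric strengths.
#' @return Named numeric vector of class `"qfd_symbol_scale"` mapping
#'   symbols (and aliases, and the empty string) to strengths.
#' @export
#' @examples
#' symbol_scale()            # 1-3-5 dialect
#' symbol_scale(strong = 9)  # 1-3-9 dialect
symbol_scale <- function(strong = 5, moderate = 3, weak = 1) {
  if (any(c(strong, moderate, weak) < 0)) {
    stop("symbol strengths must be non-negative", call. = FALSE)
  }
  structure(
    setNames(c(strong, moderate, weak, strong, moderate, weak, 0),
             c("●", "◎", "△", "S", "M", "W", "")),
    class = "qfd_symbol_scale"
  )
}

#' Parse a symbol relationship grid to numeric strengths
#'
#' @param grid Character matrix (or data frame) of relationship symbols,
#'   needs in rows, technical features in columns. Cells are trimmed;
#'   `NA` counts as blank.
#' @param scale A [symbol_scale()].
#' @return Numeric matrix of strengths with the grid's dimnames.
#' @export
parse_relationship_grid <- function(grid, scale = symbol_scale()) {
  g <- as.matrix(grid)
  g[is.na(g)] <- ""
  g <- trimws(g)
  unknown <- matrix(!(g %in% names(scale)), nrow(g))
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop(sprintf("unrecognized relationship symbol %s at row %s, column %s",
                 dQuote(g[bad[1], bad[2]]),
                 if (is.null(rownames(g))) bad[1] else rownames(g)[bad[1]],
                 if (is.null(colnames(g))) bad[2] else colnames(g)[bad[2]]),
         call. = FALSE)
  }
  # named-vector lookup cannot index the empty string, so blanks get 0 first
  v <- numeric(length(g))
  nonblank <- nzchar(g)
  v[nonblank] <- unname(scale[g[nonblank]])
  matrix(v, nrow = nrow(g), dimnames = dimnames(g))
}

#' Construct a House of Quality
#'
#' The quantitative core of the HOQ: a left wall of needs with weights
#' `W_i`, a ceiling of technical features, and a body `P` of relationship
#' strengths `P_ij`.
#'
#' @param need_weights Named non-negative numeric vector of need weights
#'   `W_i` (names are the need ids).
#' @param relationship Numeric needs x features matrix of strengths; row
#'   names must match the need ids, column names are the feature ids.
#' @return A list of class `"hoq"` with elements `needs`, `features`,
#'   `need_weights`, `P`.
#' @export
hoq <- function(need_weights, relationship) {
  P <- as.matrix(relationship)
  if (!is.numeric(P)) stop("relationship matrix must be numeric", call. = FALSE)
  if (any(P < 0)) stop("relationship strengths must be non-negative", call. = FALSE)
  if (is.null(names(need_weights)) && !is.null(rownames(P))) {
    names(need_weights) <- rownames(P)
  }
  if (!is.numeric(need_weights) || any(need_weights < 0)) {
    stop("need weights must be non-negative numbers", call. = FALSE)
  }
  if (length(need_weights) != nrow(P)) {
    stop("need weights and relationship rows disagree in length", call. = FALSE)
  }
  if (!is.null(rownames(P)) && !is.null(names(need_weights)) &&
      !identical(names(need_weights), rownames(P))) {
    if (!setequal(names(need_weights), rownames(P))) {
      stop("need ids differ between weights and relationship matrix",
           call. = FALSE)
    }
    P <- P[names(need_weights), , drop = FALSE]
  }
  features <- if (!is.null(colnames(P))) colnames(P) else paste0("f", seq_len(ncol(P)))
  colnames(P) <- features
  structure(list(needs = names(need_weights), features = features,
                 need_weights = need_weights, P = P),
            class = "hoq")
}

#' @export
print.hoq <- function(x, ...) {
  cat("House of Quality: ", length(x$needs), " needs x ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Absolute technical-feature weights
#'
#' `W_j = sum_i W_i * P_ij`: each feature's importance is the need weights
#' pushed through its relationship column.
#'
#' @param x An [hoq()].
#' @return Named numeric vector of absolute weights, one per feature.
#' @export
hoq_absolute_weights <- function(x) {
  stopifnot(inherits(x, "hoq"))
  drop(crossprod(x$P, x$need_weights))[x$features]
}

#' Relative technical-feature weights
#'
#' `W_k = W_j / sum(W_j)`; invariant under uniform rescaling of the
#' absolute weights.
#'
#' @param w_abs Named non-negative vector of absolute weights.
#' @return Named numeric vector summing to 1.
#' @export
hoq_relative_weights <- function(w_abs) {
  if (any(w_abs < 0)) stop("absolute weights must be non-negative", call. = FALSE)
  s <- sum(w_abs)
  if (s <= 0) {
    stop("degenerate House of Quality: all absolute weights are zero",
         call. = FALSE)
  }
  w_abs / s
}

# Half-up rounding (round() is banker's, which disagrees with printed
# percentage tables at exact .xx5 boundaries).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-12) / p
}

#' Rank technical features by weight
#'
#' Descending by weight; exact ties share adjacent ranks in ascending label
#' order, so the ranking is deterministic.
#'
#' @param w Named numeric vector of (absolute or relative) weights.
#' @return Integer vector of ranks, named like `w`.
#' @export
hoq_rank <- function(w) {
  if (is.null(names(w))) names(w) <- paste0("f", seq_along(w))
  ord <- order(-w, names(w))
  r <- integer(length(w))
  r[ord] <- seq_along(w)
  names(r) <- names(w)
  r
}

#' Technical-weight report for a House of Quality
#'
#' Computes absolute weights, relative weights (also as half-up-rounded
#' percentages) and ranks for every feature.
#'
#' @param x An [hoq()], or a named numeric vector of absolute weights when
#'   the relationship matrix is not available.
#' @param pct_digits Decimals for the percentage column.
#' @return A data frame of class `"hoq_report"` with columns `feature`,
#'   `absolute_weight`, `relative_weight`, `relative_pct`, `rank`.
#' @export
hoq_report <- function(x, pct_digits = 2) {
  w_abs <- if (inherits(x, "hoq")) hoq_absolute_weights(x) else x
  w_rel <- hoq_relative_weights(w_abs)
  out <- data.frame(
    feature = names(w_abs),
    absolute_weight = unname(w_abs),
    relative_weight = unname(w_rel),
    relative_pct = unname(round_half_up(100 * w_rel, pct_digits)),
    rank = unname(hoq_rank(w_rel)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("hoq_report", class(out))
  out
}

#' @export
print.hoq_report <- function(x, ...) {
  cat("Technical-feature weights (", nrow(x), " features)\n", sep = "")
  y <- as.data.frame(x)
  y$absolute_weight <- round(y$absolute_weight, 4)
  y$relative_weight <- round(y$relative_weight, 4)
  print(y[order(y$rank), ], row.names = FALSE)
  invisible(x)
}

#' Build a House of Quality report from AHP weights and a feature map
#'
#' The end-to-end Develop-stage step: needs and their comprehensive weights
#' come from an AHP weight table, the candidate feature list is consolidated
#' from a need-to-feature mapping (duplicates collapse to the first
#' occurrence), the symbol grid is parsed, and the technical weights are
#' computed and ranked.
#'
#' @param weights An `"ahp_weight_table"` from [ahp_synthesize()], or any
#'   data frame with columns `indicator` and `comprehensive_weight`.
#' @param feature_map Data frame with columns `need` and `feature` listing,
#'   per need, the technical features proposed for it.
#' @param grid Character symbol grid (needs x features); row and column
#'   names must match the mapped needs and consolidated features.
#' @param scale A [symbol_scale()].
#' @return A list of class `"hoq_build"`: `hoq`, `report` (an
#'   [hoq_report()]) and `provenance` (the deduplicated feature map).
#' @export
build_hoq_report <- function(weights, feature_map, grid,
                             scale = symbol_scale()) {
  stopifnot(is.data.frame(weights), is.data.frame(feature_map))
  if (!all(c("indicator", "comprehensive_weight") %in% names(weights))) {
    stop("weights needs columns indicator, comprehensive_weight", call. = FALSE)
  }
  if (!all(c("need", "feature") %in% names(feature_map)) ||
      nrow(feature_map) == 0L) {
    stop("feature_map needs non-empty columns need, feature", call. = FALSE)
  }
  needs <- unique(as.character(feature_map$need))
  missing <- setdiff(needs, weights$indicator)
  if (length(missing)) {
    stop("need(s) absent from the weight table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  features <- unique(as.character(feature_map$feature))  # first occurrence wins
  P <- parse_relationship_grid(grid, scale)
  if (!setequal(rownames(P), needs) || !setequal(colnames(P), features)) {
    stop("grid row/column names must match the mapped needs and features",
         call. = FALSE)
  }
  w <- weights$comprehensive_weight[match(needs, weights$indicator)]
  names(w) <- needs
  h <- hoq(w, P[needs, features, drop = FALSE])
  structure(
    list(hoq = h, report = hoq_report(h),
         provenance = unique(feature_map[, c("need", "feature")])),
    class = "hoq_build"
  )
}

#' @export
print.hoq_build <- function(x, ...) {
  print(x$hoq)
  print(x$report)
  invisible(x)
}
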