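#' Construct and validate a Saaty pairwise-comparison matrix
#'
#' A reciprocal judgement matrix on the Saaty 1--9 scale: positive entries,
#' unit diagonal, and `a_ji = 1 / a_ij` within `tol`. When the lower
#' triangle is left `NA` it is completed from the upper triangle by
#' reciprocals, which is the usual way to enter elicited judgements.
#'
#' @param x Square numeric matrix (n >= 2). `NA`s below the diagonal are
#'   filled with reciprocals of the mirrored entries.
#' @param labels Optional character vector of row/column labels; defaults to
#'   existing dimnames or `x1..xn`.
#' @param tol Reciprocity tolerance on `|a_ij * a_ji - 1|`. Judgements
#'   transcribed at limited precision (e.g. `0.333` for 1/3) need a looser
#'   tolerance such as `5e-3`.
#' @return The validated matrix with class `"pairwise_matrix"`.
#' @export
#' @examples
#' pairwise_matrix(rbind(c(1, 4, 2), c(0.25, 1, 0.5), c(0.5, 2, 1)),
#'                 labels = c("O", "A", "M"))
pairwise_matrix <- function(x, labels = NULL, tol = 1e-6) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("pairwise matrix must be numeric", call. = FALSE)
  n <- nrow(x)
  if (n != ncol(x)) stop("pairwise matrix must be square", call. = FALSE)
  if (n < 2L) stop("pairwise matrix needs n >= 2", call. = FALSE)
  # complete a lower triangle left NA from the upper triangle
  low <- which(lower.tri(x) & is.na(x), arr.ind = TRUE)
  if (nrow(low)) x[low] <- 1 / x[low[, c(2, 1), drop = FALSE]]
  if (anyNA(x)) stop("pairwise matrix has missing entries", call. = FALSE)
  if (any(x <= 0)) stop("pairwise matrix entries must be positive", call. = FALSE)
  if (any(abs(diag(x) - 1) > 1e-12)) {
    stop("pairwise matrix diagonal must be exactly 1", call. = FALSE)
  }
  recip <- abs(x * t(x) - 1)
  if (any(recip > tol)) {
    bad <- which(recip == max(recip), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "reciprocity violated at (%d,%d): %g * %g != 1 (tolerance %g)",
      bad[1], bad[2], x[bad[1], bad[2]], x[bad[2], bad[1]], tol),
      call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(x))) rownames(x) else paste0("x", seq_len(n))
  }
  if (length(labels) != n) stop("labels length must match matrix size", call. = FALSE)
  dimnames(x) <- list(labels, labels)
  class(x) <- c("pairwise_matrix", class(x))
  x
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise comparison matrix (", nrow(x), " x ", nrow(x), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Priority weights from a pairwise-comparison matrix
#'
#' Derives a normalized positive weight vector by one of three standard
#' methods:
#' \describe{
#'   \item{`"eigenvector"`}{the principal right eigenvector, computed by
#'     power iteration from a uniform start (the classical AHP
#'     prioritization); `lambda_max` is the Rayleigh quotient
#'     `mean((A w) / w)`.}
#'   \item{`"geometric"`}{normalized row geometric means (the log
#'     least-squares solution).}
#'   \item{`"colsum"`}{normalize each column to sum 1, then average rows
#'     (the sum-product approximation widely used in applied AHP studies).}
#' }
#' All three coincide on a fully consistent matrix (`a_ij = w_i / w_j`),
#' where the recovered weights are exact and `lambda_max = n`.
#'
#' @param m A [pairwise_matrix()] (a plain matrix is validated first).
#' @param method Weighting method, see above.
#' @param tol Power-iteration convergence tolerance on the max absolute
#'   change of the normalized iterate.
#' @param max_iter Power-iteration cap; non-convergence is an error.
#' @return A list of class `"ahp_weights"`: `weights` (named, summing to 1),
#'   `lambda_max`, `method`, `n`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 2), c(0.5, 1)))
#' ahp_weights(m)$weights   # 2/3, 1/3
ahp_weights <- function(m, method = c("eigenvector", "geometric", "colsum"),
                        tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  n <- nrow(m)
  A <- unclass(m)
  w <- switch(method,
    eigenvector = {
      w <- rep(1 / n, n)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        v <- drop(A %*% w)
        v <- v / sum(v)
        if (max(abs(v - w)) < tol) {
          w <- v
          converged <- TRUE
          break
        }
        w <- v
      }
      if (!converged) {
        stop("power iteration did not converge in ", max_iter, " iterations",
             call. = FALSE)
      }
      w
    },
    geometric = {
      g <- exp(rowMeans(log(A)))
      g / sum(g)
    },
    colsum = rowMeans(sweep(A, 2, colSums(A), "/"))
  )
  names(w) <- rownames(m)
  lambda_max <- mean(drop(A %*% w) / w)
  structure(list(weights = w, lambda_max = lambda_max, method = method, n = n),
            class = "ahp_weights")
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat("AHP weights (", x$method, "), lambda_max = ",
      format(round(x$lambda_max, 5)), "\n", sep = "")
  print(round(x$weights, 5))
  invisible(x)
}

#' Random-index table for the consistency ratio
#'
#' Average consistency indices of random reciprocal matrices, used as the
#' denominator of the consistency ratio. Values for n = 3..6 follow the
#' bundled case study's conventions (0.52, 0.89, 1.12, 1.26); larger sizes
#' use the standard Saaty values. Fully overridable.
#'
#' @param n Matrix order(s), 1--10.
#' @param ri_table Optional named numeric vector replacing the default.
#' @return Numeric RI value(s).
#' @export
saaty_ri <- function(n, ri_table = NULL) {
  default <- c(`1` = 0, `2` = 0, `3` = 0.52, `4` = 0.89, `5` = 1.12,
               `6` = 1.26, `7` = 1.36, `8` = 1.41, `9` = 1.46, `10` = 1.49)
  tab <- if (is.null(ri_table)) default else ri_table
  key <- as.character(n)
  if (any(!key %in% names(tab))) {
    stop("no random index configured for n = ",
         paste(setdiff(key, names(tab)), collapse = ", "), call. = FALSE)
  }
  unname(tab[key])
}

#' Consistency check of a pairwise-comparison matrix
#'
#' Computes the consistency index `CI = (lambda_max - n) / (n - 1)` and the
#' consistency ratio `CR = CI / RI`, acceptable when `CR < threshold`
#' (conventionally 0.1). For n = 2 (or whenever RI = 0) CR is defined as 0:
#' a 2 x 2 reciprocal matrix is always consistent.
#'
#' @param x A [pairwise_matrix()], an `"ahp_weights"` result, or a numeric
#'   `lambda_max` (then `n` is required).
#' @param n Matrix order; taken from `x` when it carries one.
#' @param ri_table Optional RI override passed to [saaty_ri()].
#' @param threshold CR acceptance threshold.
#' @return A list of class `"ahp_consistency"`: `lambda_max`, `n`, `CI`,
#'   `RI`, `CR`, `pass`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 4, 2), c(0.25, 1, 0.5), c(0.5, 2, 1)))
#' ahp_consistency(m)$CR   # 0: the matrix is fully consistent
ahp_consistency <- function(x, n = NULL, ri_table = NULL, threshold = 0.1) {
  if (inherits(x, "pairwise_matrix")) {
    w <- ahp_weights(x)
    lambda_max <- w$lambda_max
    n <- nrow(x)
  } else if (inherits(x, "ahp_weights")) {
    lambda_max <- x$lambda_max
    n <- x$n
  } else {
    lambda_max <- as.numeric(x)
    if (is.null(n)) stop("supply the matrix order n", call. = FALSE)
  }
  if (n < 2) stop("consistency needs n >= 2", call. = FALSE)
  # For an exactly reciprocal matrix the Rayleigh estimate satisfies
  # lambda_max >= n for any positive weight vector; judgements transcribed
  # at limited precision can undershoot by O(rounding), so only clearly
  # impossible values are rejected and small undershoots clamp CI to 0.
  if (lambda_max < n - 0.01) {
    stop("lambda_max < n is impossible for a positive reciprocal matrix",
         call. = FALSE)
  }
  ci <- max(0, (lambda_max - n) / (n - 1))
  ri <- saaty_ri(n, ri_table)
  cr <- if (ri > 0) ci / ri else 0
  structure(list(lambda_max = lambda_max, n = n, CI = ci, RI = ri, CR = cr,
                 pass = cr < threshold),
            class = "ahp_consistency")
}

#' @export
print.ahp_consistency <- function(x, ...) {
  cat(sprintf(
    "lambda_max = %.5f (n = %d)  CI = %.4f  RI = %.3f  CR = %.4f  [%s]\n",
    x$lambda_max, x$n, x$CI, x$RI, x$CR, if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Three-level AHP hierarchy
#'
#' A goal, a criterion layer with one pairwise matrix, and per-criterion
#' indicator layers each with its own pairwise matrix. Indicator labels must
#' be unique across criteria (every indicator belongs to exactly one
#' criterion) and the criterion matrix labels must match the names of the
#' indicator list.
#'
#' @param goal Goal label.
#' @param criteria [pairwise_matrix()] over the criteria.
#' @param indicators Named list of [pairwise_matrix()], one per criterion;
#'   names must equal the criterion labels.
#' @return A list of class `"ahp_hierarchy"`.
#' @export
ahp_hierarchy <- function(goal, criteria, indicators) {
  if (!inherits(criteria, "pairwise_matrix")) criteria <- pairwise_matrix(criteria)
  if (!is.list(indicators) || is.null(names(indicators))) {
    stop("indicators must be a named list of pairwise matrices", call. = FALSE)
  }
  if (!setequal(names(indicators), rownames(criteria))) {
    stop("indicator list names must match criterion labels: ",
         paste(rownames(criteria), collapse = ", "), call. = FALSE)
  }
  indicators <- lapply(indicators, function(m) {
    if (inherits(m, "pairwise_matrix")) m else pairwise_matrix(m)
  })
  all_ind <- unlist(lapply(indicators, rownames), use.names = FALSE)
  if (anyDuplicated(all_ind)) {
    stop("indicator labels duplicated across criteria: ",
         paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(goal = as.character(goal), criteria = criteria,
                 indicators = indicators[rownames(criteria)]),
            class = "ahp_hierarchy")
}

#' @export
print.ahp_hierarchy <- function(x, ...) {
  cat("AHP hierarchy: ", x$goal, "\n", sep = "")
  for (cr in rownames(x$criteria)) {
    cat("  ", cr, ": ", paste(rownames(x$indicators[[cr]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Synthesize comprehensive weights across an AHP hierarchy
#'
#' Derives criterion weights and per-criterion local indicator weights, then
#' multiplies them into comprehensive (global) weights and ranks indicators
#' in descending order. Every matrix must pass the consistency check unless
#' `force = TRUE` (then failures only warn). Rank ties are broken by
#' indicator label, ascending.
#'
#' @param hierarchy An [ahp_hierarchy()].
#' @param method Weighting method passed to [ahp_weights()].
#' @param ri_table,threshold Passed to [ahp_consistency()].
#' @param force Proceed despite failing consistency ratios.
#' @return A data frame of class `"ahp_weight_table"` with columns
#'   `criterion`, `criterion_weight`, `indicator`, `local_weight`,
#'   `comprehensive_weight`, `rank`; consistency reports are attached as
#'   `attr(, "consistency")` (named: `"criteria"` plus one per criterion).
#' @export
ahp_synthesize <- function(hierarchy, method = "eigenvector",
                           ri_table = NULL, threshold = 0.1, force = FALSE) {
  stopifnot(inherits(hierarchy, "ahp_hierarchy"))
  mats <- c(list(criteria = hierarchy$criteria), hierarchy$indicators)
  wts <- lapply(mats, ahp_weights, method = method)
  checks <- lapply(wts, function(w) {
    ahp_consistency(w, ri_table = ri_table, threshold = threshold)
  })
  failing <- names(checks)[!vapply(checks, `[[`, logical(1), "pass")]
  if (length(failing)) {
    msg <- paste0("consistency ratio >= ", threshold, " for matrix: ",
                  paste(failing, collapse = ", "))
    if (force) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  crit_w <- wts$criteria$weights
  rows <- do.call(rbind, lapply(names(hierarchy$indicators), function(cr) {
    lw <- wts[[cr]]$weights
    data.frame(criterion = cr, criterion_weight = unname(crit_w[cr]),
               indicator = names(lw), local_weight = unname(lw),
               comprehensive_weight = unname(crit_w[cr] * lw),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-rows$comprehensive_weight, rows$indicator)
  rows$rank <- integer(nrow(rows))
  rows$rank[ord] <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  attr(rows, "consistency") <- checks
  class(rows) <- c("ahp_weight_table", class(rows))
  rows
}

#' @export
print.ahp_weight_table <- function(x, ...) {
  cat("Comprehensive AHP weights (", nrow(x), " indicators)\n", sep = "")
  y <- as.data.frame(x)
  y$criterion_weight <- round(y$criterion_weight, 5)
  y$local_weight <- round(y$local_weight, 5)
  y$comprehensive_weight <- round(y$comprehensive_weight, 4)
  print(y[order(y$rank), ], row.names = FALSE)
  invisible(x)
}
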