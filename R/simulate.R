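#' Simulate Kano questionnaire responses
#'
#' Draws, for each respondent and requirement, a Kano category from the
#' requirement's target probability vector, then an answer pair uniformly
#' among the evaluation-table cells carrying that category (the
#' category-to-cell relation is many-to-one for A, I and R, so answer
#' marginals within a category are uniform over its cells).
#'
#' @param categories Named list: one element per requirement, each a
#'   probability vector named over (a subset of) the six categories and
#'   summing to 1.
#' @param n_respondents Number of respondents (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param table A [kano_evaluation_table()]. A category given positive
#'   probability but absent from the table is a specification error.
#' @return Long-format data frame with columns `respondent_id`,
#'   `requirement_id`, `functional`, `dysfunctional` (integer codes).
#' @export
#' @examples
#' r <- simulate_kano_responses(list(X1 = c(O = 1)), 5, seed = 1)
#' all(r$functional == 5 & r$dysfunctional == 1)  # O has a unique cell
simulate_kano_responses <- function(categories, n_respondents, seed = NULL,
                                    table = kano_evaluation_table()) {
  if (!is.list(categories) || is.null(names(categories)) ||
      length(categories) == 0L) {
    stop("categories must be a named list of probability vectors", call. = FALSE)
  }
  if (!is.numeric(n_respondents) || length(n_respondents) != 1L ||
      n_respondents < 1) {
    stop("n_respondents must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_respondents)
  probs <- lapply(names(categories), function(id) {
    p <- categories[[id]]
    if (is.null(names(p)) || !all(names(p) %in% kano_categories())) {
      stop("probabilities for ", id, " must be named over Kano categories",
           call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("probabilities for ", id, " must be non-negative and sum to 1",
           call. = FALSE)
    }
    full <- setNames(numeric(6), kano_categories())
    full[names(p)] <- p
    full
  })
  names(probs) <- names(categories)
  cells <- lapply(setNames(nm = kano_categories()),
                  function(k) which(table == k, arr.ind = TRUE))
  for (id in names(probs)) {
    used <- names(probs[[id]])[probs[[id]] > 0]
    empty <- used[vapply(cells[used], nrow, integer(1)) == 0L]
    if (length(empty)) {
      stop("category ", paste(empty, collapse = ", "), " for ", id,
           " has no cell in the evaluation table", call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- lapply(names(probs), function(id) {
      cat_draw <- sample(kano_categories(), n, replace = TRUE,
                         prob = probs[[id]])
      pick <- vapply(cat_draw, function(k) {
        idx <- cells[[k]]
        idx[sample.int(nrow(idx), 1L), ]
      }, numeric(2))
      data.frame(
        respondent_id = sprintf("r%03d", seq_len(n)),
        requirement_id = id,
        functional = as.integer(pick[1, ]),
        dysfunctional = as.integer(pick[2, ]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a Saaty pairwise-comparison matrix
#'
#' Builds `a_ij = (w_i / w_j) * exp(e_ij)` for `i < j` with
#' `e_ij ~ Normal(0, noise_sigma^2)`, sets `a_ji = 1 / a_ij` and the
#' diagonal to 1, so reciprocity holds by construction. With
#' `noise_sigma = 0` the matrix is fully consistent and the true weights
#' are recovered exactly. Optional snapping rounds each upper-triangle
#' entry, in log space, to the nearest value of the 1--9 scale
#' (1/9, ..., 1/2, 1, 2, ..., 9), preserving reciprocity.
#'
#' @param true_weights Positive weight vector (length >= 2); normalized
#'   internally. Names become matrix labels.
#' @param noise_sigma Standard deviation of the log-normal multiplicative
#'   perturbation (>= 0).
#' @param snap Snap entries to the Saaty scale.
#' @param seed Optional integer seed.
#' @return A [pairwise_matrix()].
#' @export
#' @examples
#' simulate_pairwise_matrix(c(4, 1, 2) / 7)  # the consistent matrix of w
simulate_pairwise_matrix <- function(true_weights, noise_sigma = 0,
                                     snap = FALSE, seed = NULL) {
  w <- true_weights
  if (!is.numeric(w) || length(w) < 2L || any(w <= 0)) {
    stop("true_weights must be >= 2 positive numbers", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  w <- w / sum(w)
  n <- length(w)
  labels <- if (!is.null(names(w))) names(w) else paste0("x", seq_len(n))
  with_seed(seed, {
    A <- diag(n)
    saaty <- c(1 / (9:2), 1, 2:9)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- (w[i] / w[j]) * exp(rnorm(1, 0, noise_sigma))
        if (snap) a <- saaty[which.min(abs(log(a) - log(saaty)))]
        A[i, j] <- a
        A[j, i] <- 1 / a
      }
    }
    pairwise_matrix(A, labels = labels)
  })
}

#' Simulate a sparse House of Quality
#'
#' Generates a needs x features relationship matrix where each cell is
#' nonzero with probability `density`, nonzero strengths are drawn from
#' `strengths` with probabilities `strength_probs`, and every need is
#' guaranteed at least one nonzero cell (a need with no related feature
#' would make its weight unusable). Need weights are drawn as normalized
#' unit-rate Gamma variates (a flat Dirichlet).
#'
#' @param n_needs,n_features Positive counts.
#' @param density Probability a cell is nonzero, in (0, 1].
#' @param strengths Possible nonzero strengths (default the 1-3-5 scale).
#' @param strength_probs Sampling probabilities over `strengths`
#'   (default uniform).
#' @param seed Optional integer seed.
#' @return An [hoq()].
#' @export
simulate_hoq <- function(n_needs, n_features, density = 0.3,
                         strengths = c(1, 3, 5), strength_probs = NULL,
                         seed = NULL) {
  if (n_needs < 1 || n_features < 1) {
    stop("n_needs and n_features must be >= 1", call. = FALSE)
  }
  if (density <= 0 || density > 1) {
    stop("density must be in (0, 1]", call. = FALSE)
  }
  if (any(strengths < 0)) stop("strengths must be non-negative", call. = FALSE)
  if (!any(strengths > 0)) stop("strengths must include a positive value", call. = FALSE)
  with_seed(seed, {
    q <- as.integer(n_needs)
    p <- as.integer(n_features)
    nz <- matrix(rbinom(q * p, 1L, density) == 1L, q, p)
    for (i in seq_len(q)) {            # guarantee >= 1 nonzero per need
      if (!any(nz[i, ])) nz[i, sample.int(p, 1L)] <- TRUE
    }
    P <- matrix(0, q, p,
                dimnames = list(paste0("need", seq_len(q)),
                                paste0("feat", seq_len(p))))
    P[nz] <- strengths[sample.int(length(strengths), sum(nz), replace = TRUE,
                                  prob = strength_probs)]
    # a guaranteed cell may still draw strength 0 when 0 is in `strengths`;
    # force those to the smallest positive strength
    pos <- min(strengths[strengths > 0])
    for (i in seq_len(q)) {
      if (all(P[i, ] == 0)) P[i, sample.int(p, 1L)] <- pos
    }
    w <- rgamma(q, 1)
    hoq(setNames(w / sum(w), rownames(P)), P)
  })
}
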