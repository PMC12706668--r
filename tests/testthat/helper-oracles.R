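# Independent oracles, written directly from the defining formulas so they
# share no code with the implementation under test.

# Literal 25-cell classification rules, keyed "functional_dysfunctional".
oracle_kano_cell <- local({
  map <- c(
    "1_1" = "Q", "1_2" = "R", "1_3" = "R", "1_4" = "R", "1_5" = "R",
    "2_1" = "M", "2_2" = "I", "2_3" = "I", "2_4" = "I", "2_5" = "R",
    "3_1" = "M", "3_2" = "I", "3_3" = "I", "3_4" = "I", "3_5" = "R",
    "4_1" = "M", "4_2" = "I", "4_3" = "I", "4_4" = "I", "4_5" = "R",
    "5_1" = "O", "5_2" = "A", "5_3" = "A", "5_4" = "A", "5_5" = "Q"
  )
  function(f, d) unname(map[paste0(f, "_", d)])
})

# Category counts by an explicit loop over response rows.
oracle_kano_counts <- function(responses) {
  counts <- c(A = 0, O = 0, M = 0, I = 0, R = 0, Q = 0)
  for (i in seq_len(nrow(responses))) {
    k <- oracle_kano_cell(responses$functional[i], responses$dysfunctional[i])
    counts[k] <- counts[k] + 1
  }
  counts
}

# Cronbach's alpha by direct summation of the variance definitions.
oracle_alpha <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  item_var <- numeric(k)
  for (j in seq_len(k)) {
    m <- sum(x[, j]) / n
    item_var[j] <- sum((x[, j] - m)^2) / (n - 1)
  }
  tot <- rowSums(x)
  mt <- sum(tot) / n
  tot_var <- sum((tot - mt)^2) / (n - 1)
  k / (k - 1) * (1 - sum(item_var) / tot_var)
}

# Partial correlation of items i and j controlling all others, via the
# residuals of two linear regressions (no matrix inversion).
oracle_partial_cor <- function(x, i, j) {
  others <- x[, -c(i, j), drop = FALSE]
  ri <- residuals(lm(x[, i] ~ others))
  rj <- residuals(lm(x[, j] ~ others))
  cor(ri, rj)
}

# KMO from raw correlations and regression-based partial correlations.
oracle_kmo <- function(x) {
  R <- cor(x)
  k <- ncol(x)
  r2 <- 0
  q2 <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r2 <- r2 + R[i, j]^2
      q2 <- q2 + oracle_partial_cor(x, i, j)^2
    }
  }
  r2 / (r2 + q2)
}

# Absolute HOQ weights by the naive double loop.
oracle_wj <- function(w, P) {
  out <- numeric(ncol(P))
  for (j in seq_len(ncol(P))) {
    for (i in seq_len(nrow(P))) out[j] <- out[j] + w[i] * P[i, j]
  }
  setNames(out, colnames(P))
}

# The published criterion- and indicator-layer matrices, entered inline so
# fixture-loading bugs cannot mask engine bugs.
study_criteria_matrix <- function() {
  pairwise_matrix(rbind(c(1, 4, 2), c(0.25, 1, 0.5), c(0.5, 2, 1)),
                  labels = c("O", "A", "M"))
}
study_emotional_matrix <- function() {
  pairwise_matrix(rbind(c(1, 3, 1), c(1 / 3, 1, 1 / 3), c(1, 3, 1)),
                  labels = paste0("A", 1:3))
}
study_safety_matrix <- function() {
  pairwise_matrix(rbind(c(1, 2, 4, 4), c(0.5, 1, 2, 2),
                        c(0.25, 0.5, 1, 1), c(0.25, 0.5, 1, 1)),
                  labels = paste0("M", 1:4))
}
study_functional_matrix <- function() {
  pairwise_matrix(rbind(
    c(1, 0.2, 0.5, 0.111, 0.125, 2),
    c(5, 1, 3, 0.5, 0.5, 8),
    c(2, 0.333, 1, 0.25, 0.25, 3),
    c(9, 2, 4, 1, 2, 9),
    c(8, 2, 4, 0.5, 1, 9),
    c(0.5, 0.125, 0.333, 0.111, 0.111, 1)),
    labels = paste0("O", 1:6), tol = 5e-3)
}

# A small consistent hierarchy used by synthesis/pipeline tests.
toy_hierarchy <- function() {
  ahp_hierarchy(
    "toy goal",
    pairwise_matrix(rbind(c(1, 2), c(0.5, 1)), labels = c("C1", "C2")),
    list(
      C1 = pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1)), labels = c("X1", "X2")),
      C2 = pairwise_matrix(rbind(c(1, 1), c(1, 1)), labels = c("Y1", "Y2"))
    )
  )
}
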