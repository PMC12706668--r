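test_that("pairwise matrix validation, reciprocal completion, errors", {
  m <- study_criteria_matrix()
  expect_s3_class(m, "pairwise_matrix")
  expect_equal(rownames(m), c("O", "A", "M"))

  expect_error(pairwise_matrix(rbind(c(1, 2), c(0.4, 1))), "reciprocity")
  expect_error(pairwise_matrix(matrix(1, 2, 3)), "square")
  expect_error(pairwise_matrix(rbind(c(1, -2), c(-0.5, 1))), "positive")
  expect_error(pairwise_matrix(rbind(c(2, 2), c(0.5, 1))), "diagonal")
  expect_error(pairwise_matrix(matrix(1, 1, 1)), "n >= 2")

  # upper-triangle-only input is completed by reciprocals
  up <- rbind(c(1, 3), c(NA, 1))
  filled <- pairwise_matrix(up)
  expect_equal(filled[2, 1], 1 / 3)

  # 3-decimal transcriptions pass only with a loosened tolerance
  expect_error(pairwise_matrix(unclass(study_functional_matrix()), tol = 1e-6),
               "reciprocity")
})

test_that("priority weights match the published consistent matrices exactly", {
  w10 <- ahp_weights(study_criteria_matrix())
  expect_equal(unname(round(w10$weights, 5)), c(0.57143, 0.14286, 0.28571))
  expect_equal(w10$lambda_max, 3, tolerance = 1e-9)

  w12 <- ahp_weights(study_safety_matrix())
  expect_equal(unname(w12$weights), c(0.5, 0.25, 0.125, 0.125),
               tolerance = 1e-10)

  # 2x2 closed form
  w2 <- ahp_weights(pairwise_matrix(rbind(c(1, 2), c(0.5, 1))))
  expect_equal(unname(w2$weights), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(w2$lambda_max, 2, tolerance = 1e-10)

  # geometric means: published emotional-needs weights, and the inconsistent
  # functional-needs matrix (frozen from a direct row-product computation)
  g11 <- ahp_weights(study_emotional_matrix(), method = "geometric")
  expect_equal(unname(round(g11$weights, 5)), c(0.42857, 0.14286, 0.42857))
  g13 <- ahp_weights(study_functional_matrix(), method = "geometric")
  expect_equal(unname(g13$weights),
               c(0.041799, 0.196550, 0.078831, 0.368175, 0.286540, 0.028105),
               tolerance = 1e-4)
  gI <- ahp_weights(pairwise_matrix(diag(3) * 0 + 1), method = "geometric")
  expect_equal(unname(gI$weights), rep(1 / 3, 3))

  # power iteration agrees with base eigen() on the inconsistent matrix
  e13 <- ahp_weights(study_functional_matrix())
  ev <- eigen(unclass(study_functional_matrix()))
  ref <- Re(ev$vectors[, 1]); ref <- ref / sum(ref)
  expect_equal(unname(e13$weights), ref, tolerance = 1e-8)
  expect_equal(e13$lambda_max, Re(ev$values[1]), tolerance = 1e-8)

  # colsum method equals the direct column-normalize/row-average computation
  A <- unclass(study_functional_matrix())
  expect_equal(unname(ahp_weights(study_functional_matrix(),
                                  method = "colsum")$weights),
               unname(rowMeans(apply(A, 2, function(col) col / sum(col)))),
               tolerance = 1e-12)
})

test_that("consistency index and ratio", {
  c10 <- ahp_consistency(study_criteria_matrix())
  expect_equal(c10$CI, 0, tolerance = 1e-9)
  expect_equal(c10$CR, 0, tolerance = 1e-9)
  expect_true(c10$pass)

  c13 <- ahp_consistency(study_functional_matrix())
  expect_equal(c13$RI, 1.26)
  expect_equal(round(c13$CI, 3), 0.022)
  expect_equal(round(c13$CR, 3), 0.018)

  # lambda_max = n gives CI = 0 at any order; n = 2 is always consistent
  expect_equal(ahp_consistency(7, n = 7)$CI, 0)
  expect_equal(ahp_consistency(2.0000001, n = 2)$CR, 0)

  # the RI table is configurable and missing orders are an error
  expect_equal(saaty_ri(3), 0.52)
  expect_equal(saaty_ri(3, ri_table = c(`3` = 0.58)), 0.58)
  w11 <- simulate_pairwise_matrix(runif(11) + 0.1, seed = 1)
  expect_error(ahp_consistency(w11), "no random index")
})

test_that("weight properties: permutation, recovery, method agreement", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    w_true <- runif(n) + 0.05
    w_true <- w_true / sum(w_true)

    # parameter recovery on consistent constructions, CR = 0
    m0 <- simulate_pairwise_matrix(w_true, noise_sigma = 0)
    for (method in c("eigenvector", "geometric", "colsum")) {
      expect_equal(unname(ahp_weights(m0, method = method)$weights),
                   unname(w_true), tolerance = 1e-8)
    }
    if (n <= 10) expect_equal(ahp_consistency(m0)$CR, 0, tolerance = 1e-9)

    # eigenvector and geometric mean coincide on consistent matrices
    expect_equal(ahp_weights(m0)$weights,
                 ahp_weights(m0, method = "geometric")$weights,
                 tolerance = 1e-10)

    # lambda_max >= n, with equality only when consistent
    mnoise <- simulate_pairwise_matrix(w_true, noise_sigma = 0.25,
                                       seed = 1000 + rep)
    expect_gte(ahp_weights(mnoise)$lambda_max, n)

    # permutation invariance up to label permutation
    perm <- sample(n)
    wp <- ahp_weights(pairwise_matrix(unclass(mnoise)[perm, perm]))
    expect_equal(unname(wp$weights),
                 unname(ahp_weights(mnoise)$weights[perm]), tolerance = 1e-9)
  }

  # near-consistent matrices: methods agree within 0.01 per component
  for (s in 1:20) {
    m <- simulate_pairwise_matrix(c(0.4, 0.3, 0.2, 0.1), noise_sigma = 0.1,
                                  seed = s)
    if (ahp_consistency(m)$CR < 0.1) {
      expect_lt(max(abs(ahp_weights(m)$weights -
                          ahp_weights(m, method = "geometric")$weights)),
                0.01)
    }
  }
})

test_that("hierarchy synthesis: conservation, gating, ranks", {
  study <- scooter_study()
  wt <- ahp_synthesize(study$hierarchy)
  expect_equal(sum(wt$comprehensive_weight), 1, tolerance = 1e-9)
  expect_equal(wt$comprehensive_weight,
               wt$criterion_weight * wt$local_weight, tolerance = 1e-12)
  expect_equal(sort(wt$rank), 1:13)
  expect_equal(round(wt$comprehensive_weight[wt$indicator == "M1"], 4), 0.1429)
  expect_equal(wt$indicator[wt$rank == 1], "O4")

  # single criterion: comprehensive weights equal local weights
  h1 <- ahp_hierarchy("g", pairwise_matrix(rbind(c(1, 1), c(1, 1)),
                                           labels = c("C1", "C2")),
                      list(C1 = study$hierarchy$indicators$M,
                           C2 = study$hierarchy$indicators$A))
  wt1 <- ahp_synthesize(h1)
  expect_equal(wt1$comprehensive_weight[wt1$criterion == "C1"],
               0.5 * wt1$local_weight[wt1$criterion == "C1"])

  # exact ties rank in ascending label order (A1 before A3)
  expect_lt(wt$rank[wt$indicator == "A1"], wt$rank[wt$indicator == "A3"])

  # consistency gate: an inconsistent matrix blocks synthesis unless forced
  bad <- pairwise_matrix(rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1)))
  hb <- ahp_hierarchy("g", pairwise_matrix(rbind(c(1, 1), c(1, 1)),
                                           labels = c("C1", "C2")),
                      list(C1 = bad, C2 = toy_hierarchy()$indicators$C2))
  expect_error(ahp_synthesize(hb), "consistency ratio")
  expect_warning(wt_f <- ahp_synthesize(hb, force = TRUE), "consistency ratio")
  expect_equal(sum(wt_f$comprehensive_weight), 1, tolerance = 1e-9)

  # hierarchy structural validation
  expect_error(ahp_hierarchy("g", study$hierarchy$criteria,
                             study$hierarchy$indicators[c("O", "A")]),
               "must match criterion labels")
  dupes <- study$hierarchy$indicators
  dupes$A <- dupes$M
  expect_error(ahp_hierarchy("g", study$hierarchy$criteria, dupes),
               "duplicated")
})
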