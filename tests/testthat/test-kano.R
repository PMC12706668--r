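test_that("the evaluation table is total over all 25 answer pairs", {
  tab <- kano_evaluation_table()
  for (f in 1:5) {
    for (d in 1:5) {
      expect_true(kano_classify(f, d, tab) %in% kano_categories())
    }
  }
  # canonical cells
  expect_equal(kano_classify("Like", "Dislike"), "O")
  expect_equal(kano_classify("Must-be", "Dislike"), "M")
  expect_equal(kano_classify("Like", "Like"), "Q")
  expect_equal(kano_classify("Neutral", "Neutral"), "I")
  # labels and codes are interchangeable
  expect_equal(kano_classify(c(5, 2), c(1, 5)), c("O", "R"))
  expect_equal(kano_classify("like", "dislike"), "O")
  # scale errors
  expect_error(kano_classify(6, 1), "invalid Kano answer")
  expect_error(kano_classify("meh", 1), "invalid Kano answer")
  # table overrides are validated
  expect_error(kano_evaluation_table(matrix("A", 4, 4)), "5 x 5")
  bad <- matrix("A", 5, 5); bad[1, 1] <- "Z"
  expect_error(kano_evaluation_table(bad), "cells must be one of")
})

test_that("tabulation counts, fractions and the modal tie-break", {
  # 32 responses: 10 one-dimensional, 18 must-be, 4 indifferent
  resp <- data.frame(
    respondent_id = sprintf("r%02d", 1:32), requirement_id = "A1",
    functional = c(rep(5, 10), rep(4, 18), rep(3, 4)),
    dysfunctional = c(rep(1, 10), rep(1, 18), rep(3, 4))
  )
  st <- kano_tabulate(resp)
  expect_equal(st$n, 32)
  expect_equal(unname(st$counts[c("O", "M", "I")]), c(10, 18, 4))
  expect_equal(unname(st$fractions[c("O", "M", "I")]),
               c(0.3125, 0.5625, 0.125))
  expect_equal(sum(st$fractions), 1, tolerance = 1e-12)
  expect_equal(kano_modal_category(st), "M")

  # one response per category is uniform
  uni <- data.frame(respondent_id = paste0("r", 1:4), requirement_id = "X",
                    functional = c(5, 5, 4, 3), dysfunctional = c(2, 1, 1, 3))
  expect_equal(unname(kano_tabulate(uni)$fractions[c("A", "O", "M", "I")]),
               rep(0.25, 4))

  # tie A = M resolves to M under the default priority, A when reordered
  tie <- c(A = 5, O = 0, M = 5, I = 0, R = 0, Q = 0)
  expect_equal(kano_modal_category(tie), "M")
  expect_equal(kano_modal_category(tie, tie_break = c("A", "O", "M", "I", "R", "Q")),
               "A")

  expect_error(kano_tabulate(resp[0, ]), "no responses")
  mixed <- resp; mixed$requirement_id[1] <- "A2"
  expect_error(kano_tabulate(mixed), "mix requirement ids")
})

test_that("Better-Worse coefficients: examples, ranges and identity", {
  # fractions A=25%, O=56.25%, M=6.25%, I=12.5%
  bw <- kano_better_worse(c(A = 8, O = 18, M = 2, I = 4, R = 0, Q = 0))
  expect_equal(unname(bw), c(0.8125, -0.625))
  expect_equal(unname(kano_better_worse(c(A = 0, O = 0, M = 0, I = 9, R = 0, Q = 0))),
               c(0, 0))
  expect_equal(unname(kano_better_worse(c(A = 0, O = 7, M = 0, I = 0, R = 0, Q = 0))),
               c(1, -1))
  expect_error(kano_better_worse(c(A = 0, O = 0, M = 0, I = 0, R = 5, Q = 1)),
               "degenerate")

  # property: ranges and SI - |DSI| = (A - M) / (A + O + M + I)
  set.seed(42)
  for (rep in 1:200) {
    counts <- setNames(as.numeric(rmultinom(1, sample(4:40, 1),
                                            prob = runif(6))),
                       kano_categories())
    denom <- sum(counts[c("A", "O", "M", "I")])
    if (denom == 0) next
    bw <- kano_better_worse(counts)
    expect_gte(bw[["SI"]], 0); expect_lte(bw[["SI"]], 1)
    expect_gte(bw[["DSI"]], -1); expect_lte(bw[["DSI"]], 0)
    expect_equal(bw[["SI"]] - abs(bw[["DSI"]]),
                 (counts[["A"]] - counts[["M"]]) / denom, tolerance = 1e-12)
  }
})

test_that("summary filters, flags, and is order-invariant and oracle-exact", {
  study <- scooter_study()
  ks <- kano_summary(study$responses)
  expect_equal(nrow(ks), 16)
  expect_equal(sort(ks$requirement_id[ks$category == "R"]),
               c("A4", "M5", "O7"))
  expect_equal(sum(ks$retained), 13)
  expect_false(any(c("A4", "M5", "O7") %in% retained_requirements(ks)))
  # scatter coordinates are |DSI| and SI
  expect_equal(ks$bw_x, abs(ks$DSI))
  expect_equal(ks$bw_y, ks$SI)

  # respondent order never changes any output
  set.seed(7)
  shuffled <- study$responses[sample(nrow(study$responses)), ]
  ks2 <- kano_summary(shuffled)
  expect_equal(attr(ks2, "counts")[rownames(attr(ks, "counts")), ],
               attr(ks, "counts"))
  ks2 <- ks2[match(ks$requirement_id, ks2$requirement_id), ]
  a1 <- as.data.frame(ks); a2 <- as.data.frame(ks2)
  attr(a1, "counts") <- attr(a2, "counts") <- NULL
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)

  # counts equal a brute-force loop with the literal 25-cell rules
  counts <- attr(ks, "counts")
  for (id in ks$requirement_id) {
    sub <- study$responses[study$responses$requirement_id == id, ]
    expect_equal(counts[id, ], oracle_kano_counts(sub))
  }

  # optional exclusion of Indifferent requirements
  ks_ri <- kano_summary(study$responses, exclude = c("R", "I"))
  expect_lte(sum(ks_ri$retained), sum(ks$retained))

  # degenerate all-Reverse requirement is flagged, not dropped
  allr <- data.frame(respondent_id = paste0("r", 1:3), requirement_id = "Z1",
                     functional = 1, dysfunctional = 4)
  kz <- kano_summary(allr)
  expect_true(is.na(kz$SI) && is.na(kz$DSI) && !kz$retained)

  # data-quality guard on Questionable-heavy requirements
  highq <- data.frame(respondent_id = paste0("r", 1:4), requirement_id = "Q1",
                      functional = c(1, 5, 5, 5), dysfunctional = c(1, 1, 1, 1))
  expect_warning(kano_summary(highq), "Questionable fraction")

  # incomplete pairs are dropped with a warning
  holes <- study$responses
  holes$functional[1] <- NA
  expect_warning(kano_summary(holes), "incomplete answer pair")
})
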