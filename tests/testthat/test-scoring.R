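test_that("base scores match hand-summed worked examples", {
  fx <- load_fixture()
  bs <- base_score(fx)
  expect_equal(bs[["064"]], 12L)   # all six traits present
  expect_equal(bs[["116"]], 7L)    # entheses + platymeric + vertebral + trauma
  expect_equal(unname(base_score(mk_assemblage(rep("unobservable", 6)))), 0L)
  expect_equal(unname(base_score(mk_assemblage(rep("absent", 6)))), 0L)
  expect_equal(unname(trait_count(mk_assemblage(rep("absent", 6)))), 0L)
})

test_that("scoring engine equals brute-force enumeration over all 729 observation vectors", {
  vecs <- all_state_vectors()
  a <- mk_assemblage(vecs, ids = sprintf("%04d", seq_len(nrow(vecs))))
  bs <- unname(base_score(a))
  bounds <- score_bounds(a)
  maxat <- unname(max_attainable(a))
  counts <- unname(trait_count(a))
  for (i in seq_len(nrow(vecs))) {
    expect_identical(bs[i], bf_score(vecs[i, ]))
    bb <- bf_bounds(vecs[i, ])
    expect_identical(bounds$score_min[i], bb[1])
    expect_identical(bounds$score_max[i], bb[2])
    expect_identical(counts[i], sum(vecs[i, ] == "present"))
    # max attainable = 12 minus weight of unobservable traits
    expect_identical(maxat[i],
                     12L - sum(ORACLE_WEIGHTS[vecs[i, ] == "unobservable"]))
  }
  # structural invariants over the full enumeration
  expect_true(all(bounds$score_min == bs))
  expect_true(all(bs <= maxat & maxat <= 12L))
  expect_true(all(bounds$score_min <= bounds$score_max &
                    bounds$score_max <= 12L))
})

test_that("score of an all-present record is 12 under any catalog row permutation", {
  a <- mk_assemblage(rep("present", 6))
  for (seed in 1:5) {
    set.seed(seed)
    perm <- trait_catalog()[sample(6), ]
    expect_equal(unname(base_score(a, catalog = perm)), 12L)
  }
})

test_that("flipping a trait from absent to present never decreases count, score or positivity", {
  set.seed(99)
  th <- hs_thresholds()
  for (rep_ in 1:40) {
    states <- sample(c("present", "absent", "unobservable"), 6, replace = TRUE)
    abs_idx <- which(states == "absent")
    if (length(abs_idx) == 0) next
    flipped <- states
    flipped[sample(abs_idx, 1)] <- "present"
    a <- mk_assemblage(rbind(states, flipped), ids = c("001", "002"))
    res <- classify(a, th, score_source = "base")
    expect_gte(res$trait_count[2], res$trait_count[1])
    expect_gte(res$base_score[2], res$base_score[1])
    expect_gte(res$positive[2], res$positive[1])
  }
})

test_that("dual-threshold classification follows both thresholds and the score source", {
  fx <- load_fixture()
  res_rep <- classify(fx, score_source = "reported")
  res_base <- classify(fx, score_source = "base")
  # both sources give the same nine positives on the published records
  expect_equal(res_rep$positive, res_base$positive)
  expect_equal(sum(res_rep$positive), 9L)
  expect_equal(res_rep$individual_id[res_rep$positive], FIXTURE_POSITIVE_IDS)
  expect_true(all(res_rep$positive ==
                    (res_rep$meets_trait_threshold &
                       res_rep$meets_point_threshold)))

  # 198: three traits, reported score 3 -> not positive
  expect_false(res_rep$positive[res_rep$individual_id == "198"])

  # degenerate thresholds make everyone positive
  expect_true(all(classify(fx, hs_thresholds(0, 0))$positive))
  # strictest thresholds leave only the all-trait individual
  strict <- classify(fx, hs_thresholds(6, 12))
  expect_equal(strict$individual_id[strict$positive], "064")

  # auto source prefers the reported score where present
  expect_true(all(classify(fx)$source_used == "reported"))
  noscore <- mk_assemblage(rep("present", 6))
  expect_equal(classify(noscore)$source_used, "base")
  expect_error(classify(noscore, score_source = "reported"),
               "reported_score missing")

  # empty assemblage classifies to an empty result
  expect_equal(nrow(classify(fx[0, ])), 0L)
})

test_that("reported scores never exceed recomputed base scores (bounded severity gap)", {
  fx <- load_fixture()
  gap <- base_score(fx) - fx$reported_score
  expect_true(all(gap >= 0L & gap <= 3L))
})

test_that("preservation flag marks negatives whose missing traits could flip the call", {
  fx <- load_fixture()
  res <- classify(fx)
  # positives are never flagged
  expect_true(all(!res$preservation_capped[res$positive]))
  # 130: three traits, base 7, ovalization (3) + vertebral (1) unpreserved:
  # a best-case completion reaches 5 traits / 11 points
  expect_true(res$preservation_capped[res$individual_id == "130"])
  # 148: fully observable except nothing missing that could help (all
  # six observable) -> can never be flagged
  expect_false(res$preservation_capped[res$individual_id == "148"])
  # an all-observable negative is never capped
  a <- mk_assemblage(c("present", "absent", "absent", "absent", "absent",
                       "absent"))
  expect_false(classify(a)$preservation_capped)
})

test_that("explicit severity deductions validate and subtract", {
  fx <- load_fixture()
  # identity: empty adjustment leaves base scores unchanged
  expect_equal(apply_adjustment(fx, data.frame()), base_score(fx))
  # deduction 1 on vertebral degeneration brings 118 from 11 to 10
  ded <- data.frame(individual_id = "118", trait_id = "vertebral",
                    deduction = 1L)
  expect_equal(apply_adjustment(fx, ded)[["118"]], 10L)
  # invalid deductions are rejected with context
  expect_error(apply_adjustment(fx, data.frame(individual_id = "118",
                                               trait_id = "trauma",
                                               deduction = 1L)),
               "not present")
  expect_error(apply_adjustment(fx, data.frame(individual_id = "118",
                                               trait_id = "vertebral",
                                               deduction = 2L)),
               "exceeds")
  expect_error(apply_adjustment(fx, data.frame(individual_id = "999",
                                               trait_id = "vertebral",
                                               deduction = 1L)),
               "unknown individual_id")
  # adjusted classification consumes the deductions
  res <- classify(fx, score_source = "adjusted", deductions = ded)
  expect_equal(res$score_used[res$individual_id == "118"], 10L)
  expect_error(classify(fx, score_source = "adjusted"), "deductions")
})

test_that("platymeric index computes the ratio and standard shape categories", {
  r <- platymeric_index(81.4, 100)
  expect_equal(r$index, 81.4)
  expect_equal(r$category, "platymeric")
  r <- platymeric_index(25, 25)
  expect_equal(r$index, 100)
  expect_equal(r$category, "stenomeric")
  # boundary goes to the upper category
  expect_equal(platymeric_index(85, 100)$category, "eurymeric")
  expect_error(platymeric_index(0, 10), "positive")
  expect_error(platymeric_index(10, -1), "positive")
})
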