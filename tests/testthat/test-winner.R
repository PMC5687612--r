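test_that("arm classification follows the futility bounds", {
  o <- classify_arm(3, design = design37)
  expect_equal(o$status, "fail_stage1")
  expect_equal(o$enrolled, 17)
  expect_equal(o$k, 3)

  o <- classify_arm(4, 10, design37)
  expect_equal(o$status, "fail_stage2")
  expect_equal(o$enrolled, 37)

  o <- classify_arm(4, 11, design37)
  expect_equal(o$status, "pass")

  expect_error(classify_arm(18, 20, design37), "x1 <= n1")
  expect_error(classify_arm(3, 5, design37), "must equal")
  expect_error(classify_arm(5, 4, design37), "x1 <= k")
  expect_error(classify_arm(5, 30, design37), "n2")
  expect_error(classify_arm(5, design = design37), "required")
})

test_that("the decision calculus maps status pairs to winners", {
  rule <- decision_rule(delta = 0.8)
  f1 <- classify_arm(2, design = design37)
  f2 <- classify_arm(5, 9, design37)
  pass_lo <- classify_arm(6, 14, design37)
  pass_hi <- classify_arm(9, 22, design37)

  # both losers, in every failing combination
  for (a in list(f1, f2)) for (b in list(f1, f2)) {
    res <- pick_winner(a, b, rule)
    expect_equal(res$winner, "none")
    expect_true(is.na(res$winner_prob))
  }
  # sample size bookkeeping: 34 when both stop early, 54 when one does
  expect_equal(pick_winner(f1, f1, rule)$total_sample_size, 34)
  expect_equal(pick_winner(f1, pass_lo, rule)$total_sample_size, 54)
  expect_equal(pick_winner(pass_lo, pass_hi, rule)$total_sample_size, 74)

  # single competitive arm wins outright, without a probability
  expect_equal(pick_winner(f1, pass_lo, rule)$winner, "B")
  expect_equal(pick_winner(f2, pass_lo, rule)$winner, "B")
  expect_equal(pick_winner(pass_lo, f1, rule)$winner, "A")
  expect_true(is.na(pick_winner(f1, pass_lo, rule)$winner_prob))

  # both competitive: thresholded posterior probability
  res <- pick_winner(pass_lo, pass_hi, rule)
  expect_equal(res$winner, "B")
  expect_gt(res$winner_prob, 0.8)
  res <- pick_winner(pass_hi, pass_lo, rule)
  expect_equal(res$winner, "A")
  expect_lt(res$winner_prob, 0.2)

  # symmetric data land in the indeterminate zone with Pr exactly 1/2
  res <- pick_winner(pass_lo, pass_lo, rule)
  expect_equal(res$winner, "none")
  expect_equal(res$winner_prob, 0.5, tolerance = 1e-9)
})

test_that("the decision is antisymmetric under arm exchange", {
  rule <- decision_rule(delta = 0.8)
  set.seed(5)
  for (i in 1:15) {
    kA <- sample(11:37, 1); kB <- sample(11:37, 1)
    a <- classify_arm(min(kA, 17), kA, design37)
    b <- classify_arm(min(kB, 17), kB, design37)
    fwd <- pick_winner(a, b, rule)
    rev <- pick_winner(b, a, rule)
    expect_equal(fwd$winner,
                 switch(rev$winner, A = "B", B = "A", none = "none"))
    if (!is.na(fwd$winner_prob))
      expect_equal(fwd$winner_prob, 1 - rev$winner_prob, tolerance = 1e-7)
  }
})

test_that("raising delta never converts an indeterminate call into a winner", {
  a <- classify_arm(6, 14, design37)
  b <- classify_arm(7, 17, design37)
  winners <- sapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95), function(d)
    pick_winner(a, b, decision_rule(delta = d))$winner)
  # once "none" appears it persists as delta rises
  seen_none <- FALSE
  for (w in winners) {
    if (seen_none) expect_equal(w, "none")
    if (w == "none") seen_none <- TRUE
  }
})

test_that("the Fisher comparator decides by the one-sided exact test", {
  rule <- decision_rule(comparator = "fisher", fisher_alpha = 0.05)
  a <- classify_arm(6, 12, design37)
  b <- classify_arm(10, 24, design37)
  res <- pick_winner(a, b, rule)
  expect_equal(res$winner, "B")
  expect_true(is.na(res$winner_prob))
  expect_equal(pick_winner(b, a, rule)$winner, "A")
  near <- pick_winner(classify_arm(6, 13, design37),
                      classify_arm(6, 15, design37), rule)
  expect_equal(near$winner, "none")
})

test_that("improper posteriors abort the decision naming the arm", {
  rule <- decision_rule(prior = prior_spec("noninformative", c = 0))
  a <- classify_arm(6, 14, design37)
  b <- classify_arm(17, 37, design37)  # all respond: b + n - k = 0 under Haldane
  expect_error(pick_winner(a, b, rule), "arm B")
})
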