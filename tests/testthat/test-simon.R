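test_that("pass probability matches brute-force double summation and its limits", {
  expect_equal(pass_probability(design37, 0), 0)
  expect_equal(pass_probability(design37, 1), 1)
  for (p in c(0.05, 0.2, 0.4, 0.7)) {
    expect_equal(pass_probability(design37, p),
                 oracle_pass_prob(17, 3, 20, 10, p), tolerance = 1e-12)
  }
  d2 <- simon_design(10, 1, 29, 5)
  for (p in c(0.1, 0.3, 0.6)) {
    expect_equal(pass_probability(d2, p),
                 oracle_pass_prob(10, 1, 19, 5, p), tolerance = 1e-12)
  }
})

test_that("pass probability is nondecreasing in the response rate", {
  for (d in list(design37, simon_design(10, 1, 29, 5))) {
    vals <- sapply(seq(0, 1, by = 0.02), function(p) pass_probability(d, p))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("stage-1 failure probability is the lower binomial tail", {
  expect_equal(stage1_fail_probability(design37, 0), 1)
  expect_equal(stage1_fail_probability(design37, 1), 0)
  direct <- sum(choose(17, 0:3) * 0.2^(0:3) * 0.8^(17 - (0:3)))
  expect_equal(stage1_fail_probability(design37, 0.2), direct, tolerance = 1e-12)
})

test_that("pass_total_pmf sums to the pass probability and has the right support", {
  for (p in c(0.1, 0.2, 0.4, 0.8)) {
    pmf <- pass_total_pmf(design37, p)
    expect_equal(sum(pmf), pass_probability(design37, p), tolerance = 1e-12)
  }
  pmf0 <- pass_total_pmf(design37, 0)
  expect_equal(sum(pmf0), 0)
  pmf <- pass_total_pmf(design37, 0.4)
  expect_equal(names(pmf), as.character(11:37))
  # all 37 patients responding is a single path
  expect_equal(unname(pmf["37"]), 0.4^37, tolerance = 1e-12)
})

test_that("design characteristics compose the per-arm summation identities", {
  h <- hypothesis(0.2, 0.4, 0.1, 0.1)
  ch <- design_characteristics(design37, h)
  expect_equal(ch$pet0, stage1_fail_probability(design37, 0.2))
  expect_equal(ch$en0, 17 + (1 - ch$pet0) * 20)
  expect_equal(ch$attained_alpha, oracle_pass_prob(17, 3, 20, 10, 0.2),
               tolerance = 1e-12)
  expect_equal(ch$attained_power, oracle_pass_prob(17, 3, 20, 10, 0.4),
               tolerance = 1e-12)
  # the published design controls both errors at 10%
  expect_lte(ch$attained_alpha, 0.10)
  expect_gte(ch$attained_power, 0.90)
  # degenerate null: certain early termination
  ch0 <- design_characteristics(design37, hypothesis(0, 0.4))
  expect_equal(ch0$pet0, 1)
  expect_equal(ch0$en0, 17)
})

test_that("optimal search recovers the published 20% vs 40% design", {
  d <- simon_search(p0 = 0.2, p1 = 0.4, alpha = 0.1, beta = 0.1)
  expect_equal(unlist(d[c("n1", "r1", "n2", "n", "r")]),
               c(n1 = 17, r1 = 3, n2 = 20, n = 37, r = 10))
  # output satisfies its own constraints when re-characterized
  ch <- design_characteristics(d, d$hypothesis)
  expect_lte(ch$attained_alpha, 0.1)
  expect_gte(ch$attained_power, 0.9)
})

test_that("optimal and minimax searches agree with a brute-force grid search", {
  opt <- oracle_simon_search(0.2, 0.4, 0.1, 0.1, nmax = 38, kind = "optimal")
  d <- simon_search(p0 = 0.2, p1 = 0.4, n_max = 38)
  expect_equal(unlist(d[c("n1", "r1", "n", "r")]),
               unlist(opt[c("n1", "r1", "n", "r")]))
  mm <- oracle_simon_search(0.2, 0.4, 0.1, 0.1, nmax = 38, kind = "minimax")
  dm <- simon_search(p0 = 0.2, p1 = 0.4, kind = "minimax", n_max = 38)
  expect_equal(unlist(dm[c("n1", "r1", "n", "r")]),
               unlist(mm[c("n1", "r1", "n", "r")]))
  expect_lte(dm$n, d$n)
})

test_that("search validates inputs and reports an exceeded bound", {
  expect_error(simon_search(p0 = 0.2, p1 = 0.2), "p1")
  expect_error(simon_search(p0 = 0.4, p1 = 0.2), "p1")
  expect_error(simon_search(p0 = 0.2, p1 = 0.4, alpha = 0.01, beta = 0.01,
                            n_max = 20), "search bound exceeded")
})

test_that("design constructor rejects inconsistent bounds", {
  expect_error(simon_design(17, 17, 37, 10), "r1 < n1")
  expect_error(simon_design(17, 3, 17, 10), "n > n1")
  expect_error(simon_design(17, 3, 37, 2), "r1 <= r")
  expect_error(simon_design(17, 3, 37, 37), "r < n")
})

test_that("enumeration agrees with Monte Carlo of the two-stage process", {
  set.seed(101)
  reps <- 1e6
  for (p in c(0.2, 0.4)) {
    est <- oracle_pass_mc(design37, p, reps)
    exact <- pass_probability(design37, p)
    se <- sqrt(exact * (1 - exact) / reps)
    expect_lt(abs(est - exact), 3 * se)
  }
})
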