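rule08 <- decision_rule(delta = 0.8)

test_that("joint status probabilities form a proper distribution", {
  scenarios <- list(c(0.2, 0.4), c(0.2, 0.35), c(0.25, 0.4), c(0.2, 0.2),
                    c(0.05, 0.6))
  for (s in scenarios) {
    oc <- exact_operating_characteristics(design37, design37, s[1], s[2], rule08)
    expect_equal(sum(oc$matrix3x3), 1, tolerance = 1e-12)
    expect_lte(oc$p_B_winner_local, oc$p_both_pass + 1e-15)
    expect_equal(oc$p_B_winner_overall,
                 oc$matrix3x3["fail_stage1", "pass"] +
                   oc$matrix3x3["fail_stage2", "pass"] + oc$p_B_winner_local,
                 tolerance = 1e-12)
    expect_equal(oc$p_B_winner_overall + oc$p_A_winner_overall + oc$p_no_winner,
                 1, tolerance = 1e-12)
  }
})

test_that("the 40% vs 20% scenario reproduces the published outcome table", {
  oc <- exact_operating_characteristics(design37, design37, 0.2, 0.4, rule08)
  expect_equal(round(100 * oc$p_B_winner_overall), 86)
  expect_lt(abs(oc$matrix3x3["fail_stage1", "pass"] - 0.50), 0.005)
  expect_lt(abs(oc$matrix3x3["fail_stage2", "pass"] - 0.32), 0.005)
  expect_equal(round(100 * oc$p_both_pass), 9)
  # local B win: published simulated 4.09%, exact within 0.1 pp
  expect_lt(abs(100 * oc$p_B_winner_local - 4.09), 0.1)
  # stopping arm A early while B wins: the published 82%
  expect_equal(round(100 * (oc$matrix3x3["fail_stage1", "pass"] +
                              oc$matrix3x3["fail_stage2", "pass"])), 82)
})

test_that("the remaining power and null scenarios match at printed rounding", {
  oc2 <- exact_operating_characteristics(design37, design37, 0.2, 0.35, rule08)
  expect_equal(round(100 * oc2$p_B_winner_overall), 71)
  expect_equal(round(100 * oc2$p_both_pass), 7)
  expect_equal(round(100 * oc2$p_B_winner_local), 2)
  oc3 <- exact_operating_characteristics(design37, design37, 0.25, 0.4, rule08)
  expect_equal(round(100 * oc3$p_B_winner_overall), 75)
  expect_equal(round(100 * oc3$p_both_pass), 26)
  expect_equal(round(100 * oc3$p_B_winner_local), 11)
  oc4 <- exact_operating_characteristics(design37, design37, 0.2, 0.2, rule08)
  expect_equal(round(100 * oc4$p_B_winner_overall), 9)
  # by symmetry the null is even-handed between the arms
  expect_equal(oc4$p_B_winner_overall, oc4$p_A_winner_overall, tolerance = 1e-12)
  # trivial: an arm that cannot respond cannot win
  oc0 <- exact_operating_characteristics(design37, design37, 0.2, 0, rule08)
  expect_equal(oc0$p_B_winner_overall, 0)
})

test_that("the threshold sweep reproduces the local power and null behaviour", {
  sw <- delta_sweep(design37, design37, 0.2, 0.4, deltas = c(0.5, 0.8, 0.9))
  expect_equal(round(100 * sw$local_B_win), c(8, 4, 2))
  # local power vanishes as delta -> 1
  sw_hi <- delta_sweep(design37, design37, 0.2, 0.4,
                       deltas = c(0.9, 0.99, 0.999))
  expect_true(all(diff(sw_hi$local_B_win) < 0))
  expect_lt(sw_hi$local_B_win[3], 0.001)

  # under the null at delta = 0.5 exactly half of the both-pass mass
  # misclassifies arm B (threshold ties split evenly)
  swn <- delta_sweep(design37, design37, 0.2, 0.2, deltas = c(0.5, 0.8, 0.9))
  expect_equal(swn$local_B_win[1], swn$p_both_pass[1] / 2, tolerance = 1e-12)
  expect_true(all(diff(swn$local_B_win) < 0))
})

test_that("the Fisher-rule comparison reproduces the published local rates", {
  # local power, one-sided 0.05: 40v20 -> 0.7%, 40v25 -> 2%, 35v20 -> 0.2%
  f1 <- fisher_rule_oc(design37, design37, 0.2, 0.4, fisher_alpha = 0.05)
  expect_equal(round(100 * f1$p_B_winner_local, 1), 0.7)
  f2 <- fisher_rule_oc(design37, design37, 0.25, 0.4, fisher_alpha = 0.05)
  expect_equal(round(100 * f2$p_B_winner_local), 2)
  f3 <- fisher_rule_oc(design37, design37, 0.2, 0.35, fisher_alpha = 0.05)
  expect_equal(round(100 * f3$p_B_winner_local, 1), 0.2)
  f4 <- fisher_rule_oc(design37, design37, 0.2, 0.2, fisher_alpha = 0.05)
  expect_lt(f4$p_B_winner_local, 1e-4)

  # the Bayesian rule at delta = 0.8 dominates the Fisher rule locally
  for (s in list(c(0.2, 0.4), c(0.25, 0.4), c(0.2, 0.35))) {
    bayes <- exact_operating_characteristics(design37, design37, s[1], s[2],
                                             rule08)
    fisher <- fisher_rule_oc(design37, design37, s[1], s[2], 0.05)
    expect_gt(bayes$p_B_winner_local, fisher$p_B_winner_local)
  }
})

test_that("overall B-win probability is nondecreasing in arm B's true rate", {
  vals <- sapply(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), function(pb)
    exact_operating_characteristics(design37, design37, 0.2, pb,
                                    rule08)$p_B_winner_overall)
  expect_true(all(diff(vals) > 0))
})

test_that("single-stage randomized comparison attains the published power", {
  pw <- crt_power(37, 0.2, 0.4, 0.09)
  expect_equal(round(100 * pw), 62)
  # null validity: attained size below the nominal one-sided level
  expect_lte(crt_power(37, 0.2, 0.2, 0.09), 0.09)
  # degenerate column: pB = 1 reduces to a single-row enumeration
  direct <- sum(dbinom(0:37, 37, 0.2) *
                  sapply(0:37, function(a)
                    oracle_fisher_enum(37, 0, a, 37 - a) < 0.09))
  expect_equal(crt_power(37, 0.2, 1, 0.09), direct, tolerance = 1e-12)
})

test_that("winner probability tracks the observed response difference", {
  m <- prob_vs_difference_map(design37, prior_spec(), pA = 0.2, pB = 0.4)
  expect_equal(nrow(m$pairs), 27^2)
  # equal counts give exactly even odds
  zero <- m$pairs[m$pairs$difference == 0, ]
  expect_true(all(abs(zero$prob - 0.5) < 1e-9))
  # spread of Pr(B>A) within each distinct difference is small among
  # outcomes the scenario can realistically produce
  expect_lt(max(m$by_difference$spread), 0.02)
  # Pr(B>A) around 0.80 corresponds to roughly a 10% difference
  bd <- m$by_difference
  i <- which.min(abs(bd$mean_prob - 0.8))
  expect_gt(bd$difference[i], 0.07)
  expect_lt(bd$difference[i], 0.13)
  # and mean Pr rises with the difference
  expect_true(all(diff(bd$mean_prob) > 0))
  # without weighting every pair is summarised
  raw <- prob_vs_difference_map(design37, prior_spec())
  expect_equal(sum(raw$by_difference$n_pairs), 27^2)
})
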