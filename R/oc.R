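#' Exact operating characteristics of the two-arm procedure
#'
#' Enumerates the joint distribution of the two arms' Simon-stage outcomes at
#' true response rates `pA` and `pB` (arms are independent given the rates)
#' and applies the winner rule to every pair of passing total-responder
#' counts, yielding exact — not simulated — operating characteristics.
#'
#' The overall probability that arm B is declared winner decomposes as
#' `P(B passes) * P(A fails) + P(both pass and the rule picks B)`; the second
#' term is the *local* power (or, under `pA = pB`, the local type I error),
#' the regime in which the threshold `delta` is active.
#'
#' Count pairs whose winner probability equals the decision threshold exactly
#' (possible only at `delta = 0.5`, where tied counts give Pr(B > A) = 1/2)
#' contribute half their mass to each arm's winner probability, reflecting
#' that at `delta = 0.5` the rule degenerates to a coin flip on ties.
#'
#' @param design_A,design_B [simon_design()] objects (may differ by arm).
#' @param pA,pB True response rates.
#' @param rule A [decision_rule()].
#' @return An object of class `"pickwinner_oc"`: a list with
#'   \item{matrix3x3}{3x3 joint status probabilities, rows arm A, columns
#'     arm B, statuses fail_stage1 / fail_stage2 / pass; sums to 1.}
#'   \item{p_both_pass}{probability both arms are competitive.}
#'   \item{p_B_winner_local, p_A_winner_local}{probability both arms pass
#'     *and* the rule declares B (resp. A).}
#'   \item{p_B_winner_overall, p_A_winner_overall}{overall winner
#'     probabilities including single-pass wins.}
#'   \item{p_no_winner}{residual probability of no declared winner.}
#'   \item{en_total}{expected total sample size.}
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' oc <- exact_operating_characteristics(d, d, pA = 0.2, pB = 0.4,
#'                                       rule = decision_rule(delta = 0.8))
#' oc$p_B_winner_overall  # overall power, ~0.86
#' @export
exact_operating_characteristics <- function(design_A, design_B, pA, pB,
                                            rule = decision_rule()) {
  stopifnot(inherits(design_A, "simon_design"),
            inherits(design_B, "simon_design"),
            inherits(rule, "decision_rule"))
  check_rate(pA, "pA"); check_rate(pB, "pB")

  statuses <- c("fail_stage1", "fail_stage2", "pass")
  marg <- function(design, p) {
    f1 <- stage1_fail_probability(design, p)
    pp <- pass_probability(design, p)
    c(fail_stage1 = f1, fail_stage2 = 1 - f1 - pp, pass = pp)
  }
  mA <- marg(design_A, pA)
  mB <- marg(design_B, pB)
  M <- outer(mA, mB)
  dimnames(M) <- list(arm_A = statuses, arm_B = statuses)

  pmfA <- pass_total_pmf(design_A, pA)
  pmfB <- pass_total_pmf(design_B, pB)
  dec <- both_pass_decision(design_A, design_B, rule)
  W <- outer(pmfA, pmfB)                       # joint mass of passing pairs
  local_B <- sum(W * dec$w_B)
  local_A <- sum(W * dec$w_A)

  overall_B <- mB[["pass"]] * (1 - mA[["pass"]]) + local_B
  overall_A <- mA[["pass"]] * (1 - mB[["pass"]]) + local_A

  en_A <- design_A$n1 + (1 - stage1_fail_probability(design_A, pA)) * design_A$n2
  en_B <- design_B$n1 + (1 - stage1_fail_probability(design_B, pB)) * design_B$n2

  structure(list(matrix3x3 = M,
                 p_both_pass = M["pass", "pass"],
                 p_B_winner_local = local_B,
                 p_A_winner_local = local_A,
                 p_B_winner_overall = overall_B,
                 p_A_winner_overall = overall_A,
                 p_no_winner = 1 - overall_B - overall_A,
                 en_total = en_A + en_B,
                 pA = pA, pB = pB, rule = rule,
                 design_A = design_A, design_B = design_B),
            class = "pickwinner_oc")
}

# Winner weights over all both-pass count pairs (kA, kB): matrices with the
# share of each pair's mass credited to a B win / A win. Bayes comparator:
# strict thresholds, with exact threshold ties split half-half (only possible
# at delta = 0.5). Fisher comparator: strict p < alpha in each direction.
both_pass_decision <- function(design_A, design_B, rule) {
  kA <- (design_A$r + 1L):design_A$n
  kB <- (design_B$r + 1L):design_B$n
  if (rule$comparator == "bayes") {
    pr <- make_priors(rule$prior)
    post_A <- lapply(kA, function(k) posterior_params(pr$A, k, design_A$n))
    post_B <- lapply(kB, function(k) posterior_params(pr$B, k, design_B$n))
    P <- vapply(post_B, function(pb)
      vapply(post_A, function(pa) prob_beta_greater(pb, pa), numeric(1)),
      numeric(length(post_A)))            # rows kA, cols kB
    eps <- 1e-9
    tie_hi <- abs(P - rule$delta) <= eps
    tie_lo <- abs(P - (1 - rule$delta)) <= eps
    w_B <- (P > rule$delta + eps) + 0.5 * tie_hi
    w_A <- (P < 1 - rule$delta - eps) + 0.5 * tie_lo
    list(w_B = w_B, w_A = w_A, prob = P, kA = kA, kB = kB)
  } else {
    pB <- vapply(kB, function(b)
      vapply(kA, function(a)
        fisher_one_sided_p(b, design_B$n - b, a, design_A$n - a, "B_greater"),
        numeric(1)),
      numeric(length(kA)))
    pA <- vapply(kB, function(b)
      vapply(kA, function(a)
        fisher_one_sided_p(b, design_B$n - b, a, design_A$n - a, "A_greater"),
        numeric(1)),
      numeric(length(kA)))
    list(w_B = (pB < rule$fisher_alpha) * 1,
         w_A = (pA < rule$fisher_alpha) * 1, kA = kA, kB = kB)
  }
}

#' @export
print.pickwinner_oc <- function(x, digits = 4, ...) {
  cat(sprintf("Exact operating characteristics (pA = %g, pB = %g)\n", x$pA, x$pB))
  print(round(x$matrix3x3, digits))
  cat(sprintf("Both arms competitive: %.2f%%\n", 100 * x$p_both_pass))
  cat(sprintf("Arm B winner: overall %.2f%% (of which local, both passing: %.2f%%)\n",
              100 * x$p_B_winner_overall, 100 * x$p_B_winner_local))
  cat(sprintf("Arm A winner: overall %.2f%% (local %.2f%%)\n",
              100 * x$p_A_winner_overall, 100 * x$p_A_winner_local))
  cat(sprintf("No winner: %.2f%%; expected total sample size %.1f\n",
              100 * x$p_no_winner, x$en_total))
  invisible(x)
}

#' Local power and type I error across winner thresholds
#'
#' Sweeps the threshold `delta` over the both-pass enumeration, reporting for
#' each value the probability that both arms pass and arm B (resp. A) is
#' declared winner. Under `pA = pB` the B column is the local
#' misclassification (type I) probability; at `delta = 0.5` threshold ties
#' are split evenly, so it equals half the both-pass probability.
#'
#' @inheritParams exact_operating_characteristics
#' @param prior A [prior_spec()].
#' @param deltas Thresholds to evaluate, each in `[0.5, 1)`.
#' @return A data frame with columns `delta`, `p_both_pass`,
#'   `local_B_win`, `local_A_win`.
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' delta_sweep(d, d, pA = 0.2, pB = 0.4, deltas = c(0.5, 0.8, 0.9))
#' @export
delta_sweep <- function(design_A, design_B, pA, pB, prior = prior_spec(),
                        deltas = c(0.5, 0.8, 0.9)) {
  stopifnot(all(deltas >= 0.5 & deltas < 1))
  pmfA <- pass_total_pmf(design_A, pA)
  pmfB <- pass_total_pmf(design_B, pB)
  W <- outer(pmfA, pmfB)
  dec <- both_pass_decision(design_A, design_B,
                            decision_rule(0.5, prior, "bayes"))
  eps <- 1e-9
  rows <- lapply(deltas, function(d) {
    tie_hi <- abs(dec$prob - d) <= eps
    tie_lo <- abs(dec$prob - (1 - d)) <= eps
    data.frame(delta = d,
               p_both_pass = sum(W),
               local_B_win = sum(W * ((dec$prob > d + eps) + 0.5 * tie_hi)),
               local_A_win = sum(W * ((dec$prob < 1 - d - eps) + 0.5 * tie_lo)))
  })
  do.call(rbind, rows)
}

#' Operating characteristics with the Fisher-test winner rule
#'
#' Same exact enumeration as [exact_operating_characteristics()], with the
#' winner among both-pass outcomes decided by a one-sided Fisher exact test
#' at level `fisher_alpha` instead of the posterior probability.
#'
#' @inheritParams exact_operating_characteristics
#' @param fisher_alpha One-sided level, strict rejection `p < fisher_alpha`.
#' @return A `"pickwinner_oc"` object (see
#'   [exact_operating_characteristics()]).
#' @export
fisher_rule_oc <- function(design_A, design_B, pA, pB, fisher_alpha = 0.05) {
  exact_operating_characteristics(
    design_A, design_B, pA, pB,
    rule = decision_rule(comparator = "fisher", fisher_alpha = fisher_alpha))
}

#' Exact power of a single-stage randomized comparison
#'
#' The benchmark standard controlled randomized trial (CRT): `n_per_arm`
#' patients per arm in a single stage, arm B declared superior when the
#' one-sided Fisher exact p-value is below `alpha_one_sided`. Power is
#' computed exactly by enumerating all binomial count pairs. Because the
#' test is discrete, the attained size under `pA = pB` is typically below
#' the nominal level.
#'
#' @param n_per_arm Patients per arm.
#' @param pA,pB True response rates.
#' @param alpha_one_sided One-sided level, strict rejection.
#' @return The rejection probability.
#' @examples
#' crt_power(37, 0.2, 0.4, 0.09)  # ~0.62
#' @export
crt_power <- function(n_per_arm, pA, pB, alpha_one_sided) {
  stopifnot(n_per_arm >= 1, n_per_arm == round(n_per_arm))
  check_rate(pA, "pA"); check_rate(pB, "pB")
  stopifnot(alpha_one_sided > 0, alpha_one_sided < 1)
  ks <- 0:n_per_arm
  P <- vapply(ks, function(b)
    vapply(ks, function(a)
      as.numeric(fisher_one_sided_p(b, n_per_arm - b, a, n_per_arm - a,
                                    "B_greater")),
      numeric(1)),
    numeric(n_per_arm + 1L))               # rows kA, cols kB
  sum(outer(stats::dbinom(ks, n_per_arm, pA),
            stats::dbinom(ks, n_per_arm, pB)) * (P < alpha_one_sided))
}

#' Winner probability versus observed response-rate difference
#'
#' Tabulates Pr(B > A) for every pair of passing total-responder counts of a
#' design used in both arms, against the observed response-rate difference
#' `(kB - kA)/n`. The winner probability tracks the difference closely: the
#' within-group spread of Pr(B > A) across pairs sharing the same difference
#' is small (< 0.02 for the 37-patient design with uniform priors), which is
#' what makes a threshold on Pr(B > A) interpretable as an approximate
#' response-difference threshold.
#'
#' @param design A [simon_design()] used for both arms.
#' @param prior A [prior_spec()]; the resulting posteriors must be proper.
#' @param pA,pB True response rates weighting the pairs. Defaults to the
#'   design's hypothesis rates (`p0`, `p1`) when the design carries them
#'   (see [simon_search()]); both `NULL` disables weighting.
#' @param min_mass Pairs with joint probability below this threshold are
#'   excluded from the per-difference summary (they still appear in
#'   `pairs`). Near the all-responders boundary the posteriors become very
#'   concentrated and Pr(B > A) departs from the difference trend, but such
#'   count pairs essentially never occur: under the weighting scenario their
#'   mass is below `min_mass`. Ignored when weighting is disabled.
#' @return A list of class `"prob_difference_map"` with
#'   \item{pairs}{data frame `kA`, `kB`, `difference`, `prob`, `mass`.}
#'   \item{by_difference}{data frame per distinct difference: `difference`,
#'     `n_pairs`, `min_prob`, `max_prob`, `mean_prob`, `spread`.}
#' @export
prob_vs_difference_map <- function(design, prior = prior_spec(),
                                   pA = NULL, pB = NULL, min_mass = 1e-8) {
  stopifnot(inherits(design, "simon_design"))
  if (is.null(pA) && !is.null(design$hypothesis)) pA <- design$hypothesis$p0
  if (is.null(pB) && !is.null(design$hypothesis)) pB <- design$hypothesis$p1
  dec <- both_pass_decision(design, design, decision_rule(0.8, prior, "bayes"))
  grid <- expand.grid(kA = dec$kA, kB = dec$kB)
  pairs <- data.frame(kA = grid$kA, kB = grid$kB,
                      difference = (grid$kB - grid$kA) / design$n,
                      prob = as.vector(dec$prob))
  weighted <- !is.null(pA) && !is.null(pB)
  pairs$mass <- if (weighted) {
    as.vector(outer(pass_total_pmf(design, pA), pass_total_pmf(design, pB)))
  } else NA_real_
  kept <- if (weighted) pairs[pairs$mass >= min_mass, ] else pairs
  sp <- split(kept$prob, round(kept$difference, 12))
  by_diff <- data.frame(
    difference = as.numeric(names(sp)),
    n_pairs = vapply(sp, length, integer(1)),
    min_prob = vapply(sp, min, numeric(1)),
    max_prob = vapply(sp, max, numeric(1)),
    mean_prob = vapply(sp, mean, numeric(1)),
    row.names = NULL)
  by_diff$spread <- by_diff$max_prob - by_diff$min_prob
  by_diff <- by_diff[order(by_diff$difference), ]
  structure(list(pairs = pairs, by_difference = by_diff, design = design,
                 prior = prior, pA = pA, pB = pB),
            class = "prob_difference_map")
}

# observed response-rate difference at which the mean winner probability
# crosses `target`, by linear interpolation over the per-difference means
difference_at_probability <- function(map, target) {
  bd <- map$by_difference
  i <- findInterval(target, bd$mean_prob)
  if (i <= 0) return(bd$difference[1])
  if (i >= nrow(bd)) return(bd$difference[nrow(bd)])
  x0 <- bd$mean_prob[i]; x1 <- bd$mean_prob[i + 1]
  bd$difference[i] + (bd$difference[i + 1] - bd$difference[i]) *
    (target - x0) / (x1 - x0)
}

#' @export
print.prob_difference_map <- function(x, ...) {
  cat(sprintf("Pr(B>A) over %d both-pass count pairs of the %d-patient design\n",
              nrow(x$pairs), x$design$n))
  cat(sprintf("Max within-difference spread of Pr(B>A): %.4f\n",
              max(x$by_difference$spread)))
  cat(sprintf("Pr(B>A) ~ 0.80 corresponds to an observed difference of about %.0f%%\n",
              100 * difference_at_probability(x, 0.8)))
  invisible(x)
}
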