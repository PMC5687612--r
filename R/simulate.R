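#' Simulate a single two-arm pick-the-winner trial
#'
#' Draws one complete trial: stage-1 responders for each arm from
#' `Binomial(n1, p)`, early stopping per the stage-1 bound, stage-2
#' responders for continuing arms, and the winner declaration via
#' [pick_winner()]. Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param design_A,design_B [simon_design()] objects.
#' @param pA,pB True response rates.
#' @param rule A [decision_rule()].
#' @return A `"trial_result"` (see [pick_winner()]).
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' set.seed(1)
#' simulate_trial(d, d, pA = 0.2, pB = 0.4)
#' @export
simulate_trial <- function(design_A, design_B, pA, pB,
                           rule = decision_rule()) {
  stopifnot(inherits(design_A, "simon_design"),
            inherits(design_B, "simon_design"))
  check_rate(pA, "pA"); check_rate(pB, "pB")
  x1A <- stats::rbinom(1L, design_A$n1, pA)
  x1B <- stats::rbinom(1L, design_B$n1, pB)
  kA <- if (x1A > design_A$r1) x1A + stats::rbinom(1L, design_A$n2, pA) else x1A
  kB <- if (x1B > design_B$r1) x1B + stats::rbinom(1L, design_B$n2, pB) else x1B
  pick_winner(classify_arm(x1A, kA, design_A),
              classify_arm(x1B, kB, design_B), rule)
}

#' Monte Carlo operating characteristics
#'
#' Simulates `reps` independent trials and summarises the joint status cells,
#' winner proportions, and mean total sample size, with binomial Monte Carlo
#' standard errors `sqrt(p(1-p)/reps)`. All randomness flows from the single
#' `seed` through a fixed draw order (stage-1 arm A, stage-1 arm B, stage-2
#' continuing arms), so results are reproducible and independent of any
#' internal batching; with `reps = 1` and the same seed the summary matches
#' [simulate_trial()] exactly.
#'
#' @inheritParams simulate_trial
#' @param reps Number of simulated trials. Default `1e5`.
#' @param seed Optional integer seed applied via [set.seed()] before drawing.
#' @return An object of class `"pickwinner_sim"`: a list with
#'   `matrix3x3` (joint status proportions), `p_both_pass`, winner
#'   proportions (`p_B_winner_overall`, `p_A_winner_overall`,
#'   `p_no_winner`, and the local `p_B_winner_local`, `p_A_winner_local`),
#'   `mean_total_n`, `reps`, and a parallel list `se` of standard errors.
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' simulate_oc(d, d, pA = 0.2, pB = 0.4, reps = 2000, seed = 42)
#' @export
simulate_oc <- function(design_A, design_B, pA, pB, rule = decision_rule(),
                        reps = 1e5, seed = NULL) {
  stopifnot(inherits(design_A, "simon_design"),
            inherits(design_B, "simon_design"),
            inherits(rule, "decision_rule"))
  check_rate(pA, "pA"); check_rate(pB, "pB")
  stopifnot(reps >= 1, reps == round(reps))
  if (!is.null(seed)) set.seed(seed)
  reps <- as.integer(reps)

  x1A <- stats::rbinom(reps, design_A$n1, pA)
  x1B <- stats::rbinom(reps, design_B$n1, pB)
  contA <- x1A > design_A$r1
  contB <- x1B > design_B$r1
  kA <- x1A
  kB <- x1B
  kA[contA] <- kA[contA] + stats::rbinom(sum(contA), design_A$n2, pA)
  kB[contB] <- kB[contB] + stats::rbinom(sum(contB), design_B$n2, pB)
  passA <- contA & kA > design_A$r
  passB <- contB & kB > design_B$r
  statA <- ifelse(!contA, 1L, ifelse(passA, 3L, 2L))
  statB <- ifelse(!contB, 1L, ifelse(passB, 3L, 2L))

  statuses <- c("fail_stage1", "fail_stage2", "pass")
  M <- table(factor(statA, 1:3, statuses), factor(statB, 1:3, statuses)) / reps
  M <- unclass(M)
  names(dimnames(M)) <- c("arm_A", "arm_B")

  # winner per replicate
  winner <- ifelse(passB & !passA, "B", ifelse(passA & !passB, "A", "none"))
  both <- passA & passB
  local_B <- local_A <- logical(reps)
  if (any(both)) {
    dec <- both_pass_decision(design_A, design_B, rule)
    iA <- kA[both] - design_A$r     # index into dec$kA
    iB <- kB[both] - design_B$r
    if (rule$comparator == "bayes") {
      prob <- dec$prob[cbind(iA, iB)]
      wb <- prob > rule$delta
      wa <- prob < 1 - rule$delta
    } else {
      wb <- dec$w_B[cbind(iA, iB)] > 0
      wa <- dec$w_A[cbind(iA, iB)] > 0
    }
    winner[both][wb] <- "B"
    winner[both][wa] <- "A"
    local_B[both] <- wb
    local_A[both] <- wa
  }
  totalN <- ifelse(contA, design_A$n, design_A$n1) +
    ifelse(contB, design_B$n, design_B$n1)

  prop <- function(x) mean(x)
  se <- function(p) sqrt(p * (1 - p) / reps)
  est <- list(p_both_pass = prop(both),
              p_B_winner_overall = prop(winner == "B"),
              p_A_winner_overall = prop(winner == "A"),
              p_no_winner = prop(winner == "none"),
              p_B_winner_local = prop(local_B),
              p_A_winner_local = prop(local_A))
  structure(c(list(matrix3x3 = M), est,
              list(se = lapply(est, se),
                   mean_total_n = mean(totalN),
                   reps = reps, pA = pA, pB = pB, rule = rule,
                   seed = seed)),
            class = "pickwinner_sim")
}

#' @export
print.pickwinner_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo operating characteristics (%d trials, pA = %g, pB = %g)\n",
              x$reps, x$pA, x$pB))
  print(round(x$matrix3x3, digits))
  cat(sprintf("Arm B winner: %.2f%% (SE %.2f pp); arm A: %.2f%%; none: %.2f%%\n",
              100 * x$p_B_winner_overall, 100 * x$se$p_B_winner_overall,
              100 * x$p_A_winner_overall, 100 * x$p_no_winner))
  cat(sprintf("Both competitive: %.2f%%; mean total sample size %.1f\n",
              100 * x$p_both_pass, x$mean_total_n))
  invisible(x)
}
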