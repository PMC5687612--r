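#' Winner decision rule
#'
#' The rule applied when both arms pass the second stage. Under the Bayesian
#' comparator, arm B is the winner if `Pr(B > A) > delta` and arm A if
#' `Pr(B > A) < 1 - delta`; in between, no clear winner is declared. Under
#' the Fisher comparator, the winner is the arm favoured by a one-sided
#' Fisher exact test with `p < fisher_alpha`.
#'
#' @param delta Winner threshold, in `[0.5, 1)`. Default 0.8, at which the
#'   threshold corresponds to roughly a 10 percentage-point difference in
#'   observed response rates for trials of ~37 patients per arm.
#' @param prior A [prior_spec()] for the posterior comparison. Default
#'   uniform `beta(1, 1)` in both arms.
#' @param comparator `"bayes"` (default) or `"fisher"`.
#' @param fisher_alpha One-sided significance level for the Fisher
#'   comparator. Default 0.05.
#' @return An object of class `"decision_rule"`.
#' @export
decision_rule <- function(delta = 0.8, prior = prior_spec(),
                          comparator = c("bayes", "fisher"),
                          fisher_alpha = 0.05) {
  comparator <- match.arg(comparator)
  stopifnot(is.numeric(delta), length(delta) == 1L)
  if (!(delta >= 0.5 && delta < 1)) stop("'delta' must lie in [0.5, 1)")
  stopifnot(inherits(prior, "prior_spec"))
  if (comparator == "fisher") {
    stopifnot(is.numeric(fisher_alpha), length(fisher_alpha) == 1L)
    if (!(fisher_alpha > 0 && fisher_alpha < 1))
      stop("'fisher_alpha' must lie in (0, 1)")
  }
  structure(list(delta = delta, prior = prior, comparator = comparator,
                 fisher_alpha = fisher_alpha),
            class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  if (x$comparator == "bayes") {
    cat(sprintf("Bayesian winner rule: B wins if Pr(B>A) > %g, A wins if Pr(B>A) < %g (prior family '%s')\n",
                x$delta, 1 - x$delta, x$prior$family))
  } else {
    cat(sprintf("Fisher winner rule: one-sided exact test at p < %g\n",
                x$fisher_alpha))
  }
  invisible(x)
}

#' Classify one arm's outcome under its Simon design
#'
#' @param x1 Stage-1 responders, `0 <= x1 <= n1`.
#' @param k Total responders. If the arm stops at stage 1 (`x1 <= r1`), `k`
#'   must equal `x1` (or be omitted); otherwise `x1 <= k <= n` with
#'   `k - x1 <= n2`.
#' @param design A [simon_design()].
#' @return An object of class `"arm_outcome"`: a list with `x1`, `k`,
#'   `enrolled` (`n1` on early stopping, `n` otherwise) and `status`, one of
#'   `"fail_stage1"`, `"fail_stage2"`, `"pass"`.
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' classify_arm(3, design = d)          # stopped early
#' classify_arm(4, 11, design = d)      # competitive arm
#' @export
classify_arm <- function(x1, k = NULL, design) {
  stopifnot(inherits(design, "simon_design"),
            is.numeric(x1), length(x1) == 1L, x1 == round(x1))
  if (x1 < 0 || x1 > design$n1) stop("need 0 <= x1 <= n1")
  if (x1 <= design$r1) {
    if (!is.null(k) && k != x1)
      stop("arm stops at stage 1 (x1 <= r1); 'k' must equal 'x1'")
    return(structure(list(x1 = as.integer(x1), k = as.integer(x1),
                          enrolled = design$n1, status = "fail_stage1"),
                     class = "arm_outcome"))
  }
  if (is.null(k)) stop("arm continues to stage 2; total responders 'k' required")
  stopifnot(is.numeric(k), length(k) == 1L, k == round(k))
  if (k < x1 || k - x1 > design$n2)
    stop("need x1 <= k <= x1 + n2 for an arm reaching stage 2")
  structure(list(x1 = as.integer(x1), k = as.integer(k), enrolled = design$n,
                 status = if (k <= design$r) "fail_stage2" else "pass"),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm outcome: %d/%d responders (stage 1: %d), status %s\n",
              x$k, x$enrolled, x$x1, x$status))
  invisible(x)
}

#' Declare the trial winner
#'
#' The pick-the-winner decision calculus. If neither arm passes the second
#' stage, both are losers and no winner is claimed. If exactly one arm
#' passes, it is the winner outright. If both arms are competitive, the
#' winner is decided by the [decision_rule()] — by Pr(B > A) against
#' `delta`, or by the one-sided Fisher exact test.
#'
#' @param outcome_A,outcome_B [classify_arm()] results for arms A and B.
#' @param rule A [decision_rule()].
#' @return An object of class `"trial_result"`: a list with `outcome_A`,
#'   `outcome_B`, `winner` (`"A"`, `"B"` or `"none"`), `winner_prob`
#'   (Pr(B > A) when both arms are competitive under the Bayesian
#'   comparator, `NA` otherwise) and `total_sample_size`.
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' pick_winner(classify_arm(3, design = d), classify_arm(6, 14, design = d),
#'             decision_rule(delta = 0.8))
#' @export
pick_winner <- function(outcome_A, outcome_B, rule = decision_rule()) {
  stopifnot(inherits(outcome_A, "arm_outcome"),
            inherits(outcome_B, "arm_outcome"),
            inherits(rule, "decision_rule"))
  total_n <- outcome_A$enrolled + outcome_B$enrolled
  a_pass <- outcome_A$status == "pass"
  b_pass <- outcome_B$status == "pass"
  winner <- "none"
  prob <- NA_real_
  if (a_pass && b_pass) {
    if (rule$comparator == "bayes") {
      pr <- make_priors(rule$prior)
      post_A <- tryCatch(posterior_params(pr$A, outcome_A$k, outcome_A$enrolled),
                         error = function(e)
                           stop("arm A: ", conditionMessage(e), call. = FALSE))
      post_B <- tryCatch(posterior_params(pr$B, outcome_B$k, outcome_B$enrolled),
                         error = function(e)
                           stop("arm B: ", conditionMessage(e), call. = FALSE))
      prob <- prob_beta_greater(post_B, post_A)
      winner <- if (prob > rule$delta) "B"
                else if (prob < 1 - rule$delta) "A" else "none"
    } else {
      pB <- fisher_one_sided_p(outcome_B$k, outcome_B$enrolled - outcome_B$k,
                               outcome_A$k, outcome_A$enrolled - outcome_A$k,
                               direction = "B_greater")
      pA <- fisher_one_sided_p(outcome_B$k, outcome_B$enrolled - outcome_B$k,
                               outcome_A$k, outcome_A$enrolled - outcome_A$k,
                               direction = "A_greater")
      winner <- if (pB < rule$fisher_alpha) "B"
                else if (pA < rule$fisher_alpha) "A" else "none"
    }
  } else if (b_pass) {
    winner <- "B"
  } else if (a_pass) {
    winner <- "A"
  }
  structure(list(outcome_A = outcome_A, outcome_B = outcome_B,
                 winner = winner, winner_prob = prob,
                 total_sample_size = total_n),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Two-arm pick-the-winner trial result\n")
  cat(sprintf("  Arm A: %d/%d responders, %s\n",
              x$outcome_A$k, x$outcome_A$enrolled, x$outcome_A$status))
  cat(sprintf("  Arm B: %d/%d responders, %s\n",
              x$outcome_B$k, x$outcome_B$enrolled, x$outcome_B$status))
  if (!is.na(x$winner_prob))
    cat(sprintf("  Pr(B > A) = %.4f\n", x$winner_prob))
  cat(sprintf("  Winner: %s; total sample size %d\n",
              if (x$winner == "none") "none (no clear winner)" else
                paste("arm", x$winner),
              x$total_sample_size))
  invisible(x)
}
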