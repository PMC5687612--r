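#' Design a Bayesian pick-the-winner randomized phase II trial
#'
#' The central constructor of the package. Searches a Simon two-stage design
#' for each arm (by default the same hypothesis in both arms) and attaches
#' the winner rule, producing an object from which operating characteristics
#' ([summary()]), simulated trials ([simulate()]), the winner-probability
#' map ([plot()]) and a protocol statistical plan ([statistical_plan()]) are
#' derived.
#'
#' @param p0 Unacceptable response rate (both arms unless `h_A`/`h_B` given).
#' @param p1 Promising response rate.
#' @param alpha,beta Per-arm maximum type I / II error rates. Default 0.10.
#' @param delta Winner threshold for Pr(B > A). Default 0.8.
#' @param prior A [prior_spec()]. Default uniform `beta(1, 1)` in both arms.
#' @param kind Simon search objective, `"optimal"` (default) or `"minimax"`.
#' @param n_max Search bound on the per-arm total sample size. Default 100.
#' @param h_A,h_B Optional per-arm [hypothesis()] objects overriding
#'   `p0`/`p1`/`alpha`/`beta`, allowing the arms to differ.
#'
#' @return An object of class `"ptw_design"`: a list with `design_A`,
#'   `design_B` (each a [simon_design()] with characteristics), and `rule`
#'   (a [decision_rule()]).
#' @examples
#' tr <- ptw_design(p0 = 0.2, p1 = 0.4, alpha = 0.1, beta = 0.1, delta = 0.8)
#' tr
#' summary(tr)
#' @export
ptw_design <- function(p0, p1, alpha = 0.10, beta = 0.10, delta = 0.8,
                       prior = prior_spec(), kind = c("optimal", "minimax"),
                       n_max = 100, h_A = NULL, h_B = NULL) {
  kind <- match.arg(kind)
  if (is.null(h_A)) h_A <- hypothesis(p0, p1, alpha, beta)
  if (is.null(h_B)) h_B <- h_A
  design_A <- simon_search(h_A, kind = kind, n_max = n_max)
  design_B <- if (identical(h_A, h_B)) design_A
              else simon_search(h_B, kind = kind, n_max = n_max)
  structure(list(design_A = design_A, design_B = design_B,
                 rule = decision_rule(delta = delta, prior = prior)),
            class = "ptw_design")
}

#' @export
print.ptw_design <- function(x, ...) {
  cat("Bayesian pick-the-winner design (two-arm randomized phase II)\n\n")
  same <- identical(x$design_A[c("n1", "r1", "n", "r")],
                    x$design_B[c("n1", "r1", "n", "r")])
  if (same) {
    cat("Both arms:\n")
    print(x$design_A)
  } else {
    cat("Arm A:\n"); print(x$design_A)
    cat("Arm B:\n"); print(x$design_B)
  }
  cat("\n")
  print(x$rule)
  cat(sprintf("Total sample size: %d (both stop early) to %d (both complete)\n",
              x$design_A$n1 + x$design_B$n1, x$design_A$n + x$design_B$n))
  invisible(x)
}

#' Operating characteristics of a pick-the-winner design
#'
#' Computes exact operating characteristics for a set of true response-rate
#' scenarios. The default scenarios are the design's alternative
#' (`pA = p0`, `pB = p1`) and null (`pA = pB = p0`).
#'
#' @param object A [ptw_design()].
#' @param scenarios A list of length-2 numeric vectors `c(pA, pB)`.
#' @param ... Unused.
#' @return A list of class `"summary.ptw_design"`: one
#'   [exact_operating_characteristics()] result per scenario.
#' @export
summary.ptw_design <- function(object, scenarios = NULL, ...) {
  hA <- object$design_A$hypothesis
  hB <- object$design_B$hypothesis
  if (is.null(scenarios))
    scenarios <- list(c(hA$p0, hB$p1), c(hA$p0, hA$p0))
  out <- lapply(scenarios, function(s) {
    stopifnot(is.numeric(s), length(s) == 2L)
    exact_operating_characteristics(object$design_A, object$design_B,
                                    pA = s[1], pB = s[2], rule = object$rule)
  })
  structure(out, class = "summary.ptw_design", design = object)
}

#' @export
print.summary.ptw_design <- function(x, ...) {
  for (i in seq_along(x)) {
    cat(sprintf("-- Scenario %d --\n", i))
    print(x[[i]])
    cat("\n")
  }
  invisible(x)
}

#' Simulate trials from a pick-the-winner design
#'
#' With `nsim = 1` returns a single `"trial_result"`; with `nsim > 1`
#' returns the Monte Carlo summary of [simulate_oc()].
#'
#' @param object A [ptw_design()].
#' @param nsim Number of trials.
#' @param seed Optional seed.
#' @param pA,pB True response rates; default the design's null rate for A and
#'   promising rate for B.
#' @param ... Unused.
#' @return A `"trial_result"` or a `"pickwinner_sim"`.
#' @importFrom stats simulate
#' @export
simulate.ptw_design <- function(object, nsim = 1, seed = NULL,
                                pA = object$design_A$hypothesis$p0,
                                pB = object$design_B$hypothesis$p1, ...) {
  if (nsim == 1) {
    if (!is.null(seed)) set.seed(seed)
    simulate_trial(object$design_A, object$design_B, pA, pB, object$rule)
  } else {
    simulate_oc(object$design_A, object$design_B, pA, pB, object$rule,
                reps = nsim, seed = seed)
  }
}

#' Plot the winner probability against the observed response difference
#'
#' Displays Pr(B > A) for every both-pass count pair against the observed
#' response-rate difference, with the decision thresholds `delta` and
#' `1 - delta` marked. Requires both arms to share a design.
#'
#' @param x A [ptw_design()].
#' @param ... Passed to [graphics::plot()].
#' @return The [prob_vs_difference_map()], invisibly.
#' @export
plot.ptw_design <- function(x, ...) {
  m <- prob_vs_difference_map(x$design_B, x$rule$prior)
  graphics::plot(m$pairs$difference, m$pairs$prob,
                 xlab = "Observed response-rate difference (B - A)",
                 ylab = "Pr(B > A)", pch = 16, cex = 0.5, ...)
  graphics::abline(h = c(x$rule$delta, 1 - x$rule$delta), lty = 2)
  invisible(m)
}
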