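#' One-sided Fisher exact test for a 2x2 response table
#'
#' Conditional on the table margins, the responder count in arm B follows a
#' hypergeometric distribution; the one-sided p-value in the `B_greater`
#' direction is the upper tail `P(X >= kB)` (the observed table included, the
#' standard Fisher convention), and symmetrically `P(X <= kB)` for
#' `A_greater`.
#'
#' @param kB,fB Responders and non-responders in arm B.
#' @param kA,fA Responders and non-responders in arm A.
#' @param direction `"B_greater"` (default) or `"A_greater"`.
#' @return The one-sided p-value, in `(0, 1]`. When no responders (or no
#'   non-responders) occur at all the table carries no directional
#'   information and the p-value is 1, with attribute
#'   `"degenerate" = TRUE`.
#' @examples
#' fisher_one_sided_p(31, 7, 20, 20)  # 0.003
#' fisher_one_sided_p(6, 33, 2, 39)   # 0.12
#' @export
fisher_one_sided_p <- function(kB, fB, kA, fA,
                               direction = c("B_greater", "A_greater")) {
  direction <- match.arg(direction)
  counts <- c(kB = kB, fB = fB, kA = kA, fA = fA)
  stopifnot(is.numeric(counts), all(counts == round(counts)))
  if (any(counts < 0)) stop("table counts must be nonnegative")
  nB <- kB + fB
  nA <- kA + fA
  if (nB == 0 || nA == 0) stop("each arm must contain at least one subject")
  m <- kB + kA            # total responders
  if (m == 0 || m == nA + nB) {
    return(structure(1, degenerate = TRUE))
  }
  p <- if (direction == "B_greater") {
    stats::phyper(kB - 1, m, nA + nB - m, nB, lower.tail = FALSE)
  } else {
    stats::phyper(kB, m, nA + nB - m, nB)
  }
  as.numeric(p)
}

#' Equivalence of the unfavorable-arm-B prior and the Fisher exact test
#'
#' With the improper prior pair `beta(1, 0)` in arm A and `beta(0, 1)` in arm
#' B (the unfavorable-arm-B family at `c = 1`), the posterior winner
#' probability and the one-sided Fisher exact test are two faces of the same
#' quantity (Altham 1969): `Pr(B > A) = 1 - p` where `p` is the one-sided
#' p-value in the `B_greater` direction. This function computes both sides
#' and their discrepancy `|Pr(B > A) + p - 1|`.
#'
#' The posteriors are `beta(kB, fB + 1)` and `beta(kA + 1, fA)`, so the
#' identity requires `kB >= 1` and `fA >= 1` for properness.
#'
#' @inheritParams fisher_one_sided_p
#' @return A list with `prob` (Pr(B > A) under the unfavorable `c = 1`
#'   prior), `fisher_p` (one-sided p, `B_greater`) and `discrepancy`.
#' @examples
#' altham_identity_check(2, 0, 0, 2)  # prob 5/6, p 1/6
#' @export
altham_identity_check <- function(kB, fB, kA, fA) {
  if (kB < 1) stop("identity requires kB >= 1 (arm B posterior properness)")
  if (fA < 1) stop("identity requires fA >= 1 (arm A posterior properness)")
  pr <- make_priors(prior_spec("unfavorable_B", c = 1))
  post_B <- posterior_params(pr$B, kB, kB + fB)
  post_A <- posterior_params(pr$A, kA, kA + fA)
  prob <- prob_beta_greater(post_B, post_A)
  p <- fisher_one_sided_p(kB, fB, kA, fA, direction = "B_greater")
  list(prob = prob, fisher_p = as.numeric(p),
       discrepancy = abs(prob + as.numeric(p) - 1))
}
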