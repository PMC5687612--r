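#' Probability one beta random variable exceeds another
#'
#' Computes `P(X > Y)` for independent `X ~ Beta(a_B, b_B)` and
#' `Y ~ Beta(a_A, b_A)` — with posterior parameters, the winner probability
#' Pr(B > A) that arm B's true response rate exceeds arm A's.
#'
#' When either pair of shapes is integer-valued the probability is evaluated
#' in closed form: writing `m = a_A + b_A - 1`, the beta CDF with integer
#' shapes is a binomial tail, so
#' `P(X > Y) = sum_{j = a_A}^{m} choose(m, j) B(a_B + j, b_B + m - j) / B(a_B, b_B)`,
#' accumulated on the log scale. Otherwise `P(X > Y) = int f_X(x) F_Y(x) dx`
#' is evaluated by adaptive quadrature to relative tolerance `tol`. Both X
#' and Y are continuous, so ties have probability zero and `P(X > Y)` equals
#' `P(X >= Y)`.
#'
#' @param params_B Shape pair of X (arm B), a [beta_params()]; must be proper.
#' @param params_A Shape pair of Y (arm A); must be proper.
#' @param tol Accuracy of the quadrature fallback. Default `1e-8`.
#' @return `P(X > Y)`, a number in `[0, 1]`.
#' @examples
#' prob_beta_greater(beta_params(32, 8), beta_params(21, 21))  # 0.998
#' prob_beta_greater(beta_params(2, 1), beta_params(1, 1))     # 2/3
#' @export
prob_beta_greater <- function(params_B, params_A, tol = 1e-8) {
  params_B <- beta_params(params_B[[1]], params_B[[2]])
  params_A <- beta_params(params_A[[1]], params_A[[2]])
  if (!is_proper(params_B)) stop("arm B distribution is improper")
  if (!is_proper(params_A)) stop("arm A distribution is improper")
  if (is_integer_pair(params_A)) {
    beta_exceed_integer(params_B, params_A)
  } else if (is_integer_pair(params_B)) {
    1 - beta_exceed_integer(params_A, params_B)
  } else {
    f <- function(x) {
      stats::dbeta(x, params_B[["a"]], params_B[["b"]]) *
        stats::pbeta(x, params_A[["a"]], params_A[["b"]])
    }
    stats::integrate(f, 0, 1, rel.tol = tol, abs.tol = tol,
                     subdivisions = 1000L)$value
  }
}

is_integer_pair <- function(params, eps = 1e-9) {
  all(abs(params - round(params)) < eps)
}

# P(X > Y) with Y ~ Beta(aA, bA), aA and bA integers, X ~ Beta(aB, bB) any
# proper pair: F_Y(x) = sum_{j >= aA} choose(m, j) x^j (1-x)^(m-j), m = aA+bA-1,
# and each term integrates against f_X to a ratio of beta functions.
beta_exceed_integer <- function(params_B, params_A) {
  aB <- params_B[["a"]]; bB <- params_B[["b"]]
  aA <- round(params_A[["a"]]); bA <- round(params_A[["b"]])
  m <- aA + bA - 1
  j <- aA:m
  min(1, sum(exp(lchoose(m, j) + lbeta(aB + j, bB + m - j) - lbeta(aB, bB))))
}

#' Winner probability under a list of prior specifications
#'
#' Evaluates Pr(B > A) for fixed trial outcomes `kA/nA` and `kB/nB` under each
#' prior specification, to assess prior sensitivity. Specifications whose
#' posterior is improper for these data are flagged rather than dropped.
#'
#' @param kA,nA Responders and enrolled in arm A.
#' @param kB,nB Responders and enrolled in arm B.
#' @param specs A list of [prior_spec()] objects.
#' @param tol Passed to [prob_beta_greater()].
#' @return A data frame with one row per spec: `family`, `c`, `sd`,
#'   `proper` (posterior properness) and `prob` (`NA` where improper).
#' @examples
#' specs <- lapply(c(0, 0.5, 1), function(c) prior_spec("noninformative", c))
#' prior_sensitivity(8, 37, 15, 37, specs)
#' @export
prior_sensitivity <- function(kA, nA, kB, nB, specs, tol = 1e-8) {
  stopifnot(is.list(specs), length(specs) > 0)
  rows <- lapply(specs, function(spec) {
    stopifnot(inherits(spec, "prior_spec"))
    pr <- make_priors(spec)
    res <- tryCatch({
      post_A <- posterior_params(pr$A, kA, nA)
      post_B <- posterior_params(pr$B, kB, nB)
      list(proper = TRUE, prob = prob_beta_greater(post_B, post_A, tol))
    }, error = function(e) list(proper = FALSE, prob = NA_real_))
    data.frame(family = spec$family,
               c = if (spec$family == "moments") NA_real_ else spec$c,
               sd = if (spec$family == "moments") spec$sd else NA_real_,
               proper = res$proper, prob = res$prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
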