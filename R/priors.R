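#' Beta shape-parameter pair
#'
#' Light validation helper for a pair of beta shape parameters `c(a, b)`.
#' Improper pairs (a zero shape) are representable — several reference priors
#' below are improper — but any distribution actually used for probability
#' computation must be proper (`a > 0` and `b > 0`).
#'
#' @param a,b Nonnegative shape parameters.
#' @return A named numeric vector `c(a = a, b = b)`.
#' @export
beta_params <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (is.na(a) || is.na(b) || a < 0 || b < 0)
    stop("beta shape parameters must be nonnegative")
  c(a = as.numeric(a), b = as.numeric(b))
}

is_proper <- function(params) all(params > 0)

#' Specify a prior family for the two-arm comparison
#'
#' The four prior families used to study sensitivity of the winner
#' probability:
#' \describe{
#'   \item{`"noninformative"`}{`beta(c, c)` in both arms; `c = 0` (Haldane),
#'     `0.5` (Jeffreys) and `1` (uniform) are the usual choices.}
#'   \item{`"unfavorable_B"`}{`beta(c, 0)` in arm A and `beta(0, c)` in arm B
#'     — an improper pair tilting the comparison against arm B. At `c = 1`
#'     this reproduces the one-sided Fisher exact test (see
#'     [altham_identity_check()]).}
#'   \item{`"favorable_B"`}{`beta(0, c)` in arm A and `beta(c, 0)` in arm B,
#'     the mirror image.}
#'   \item{`"moments"`}{proper per-arm priors matched to a hypothesized or
#'     observed response rate (`mean_A`, `mean_B`) with common standard
#'     deviation `sd` (default 0.1) via [prior_from_moments()].}
#' }
#'
#' @param family One of `"noninformative"`, `"unfavorable_B"`,
#'   `"favorable_B"`, `"moments"`.
#' @param c Scale parameter for families i--iii; nonnegative. Default 1.
#' @param mean_A,mean_B Prior mean response rates in `(0, 1)` (family iv).
#' @param sd Prior standard deviation (family iv). Default 0.1.
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec()                                # uniform beta(1,1) both arms
#' prior_spec("unfavorable_B", c = 1)          # Fisher-equivalent pair
#' prior_spec("moments", mean_A = 0.2, mean_B = 0.4, sd = 0.1)
#' @export
prior_spec <- function(family = c("noninformative", "unfavorable_B",
                                  "favorable_B", "moments"),
                       c = 1, mean_A = NULL, mean_B = NULL, sd = 0.1) {
  family <- match.arg(family)
  if (family == "moments") {
    if (is.null(mean_A) || is.null(mean_B))
      stop("family 'moments' requires 'mean_A' and 'mean_B'")
    # validate representability up front
    prior_from_moments(mean_A, sd)
    prior_from_moments(mean_B, sd)
  } else {
    stopifnot(is.numeric(c), length(c) == 1L)
    if (is.na(c) || c < 0) stop("'c' must be nonnegative")
  }
  structure(list(family = family, c = c, mean_A = mean_A, mean_B = mean_B,
                 sd = sd),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  pr <- make_priors(x)
  cat(sprintf("Prior family '%s': arm A beta(%g, %g), arm B beta(%g, %g)%s\n",
              x$family, pr$A["a"], pr$A["b"], pr$B["a"], pr$B["b"],
              if (!is_proper(pr$A) || !is_proper(pr$B))
                " [improper until updated]" else ""))
  invisible(x)
}

#' Beta parameters matched to a mean and standard deviation
#'
#' Method-of-moments inversion: for mean `m` and variance `v < m(1-m)`,
#' `a = m (m(1-m)/v - 1)` and `b = a (1-m)/m`.
#'
#' @param mean Prior mean response rate, in `(0, 1)`.
#' @param sd Prior standard deviation; must satisfy `sd^2 < mean*(1-mean)`.
#' @return A [beta_params()] pair.
#' @examples
#' prior_from_moments(0.4, 0.1)  # beta(9.2, 13.8)
#' @export
prior_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L,
            length(sd) == 1L)
  if (!(mean > 0 && mean < 1)) stop("'mean' must lie in (0, 1)")
  v <- sd^2
  if (!(v > 0 && v < mean * (1 - mean)))
    stop("'sd' not representable: need 0 < sd^2 < mean * (1 - mean)")
  a <- mean * (mean * (1 - mean) / v - 1)
  beta_params(a, a * (1 - mean) / mean)
}

#' Realise the per-arm beta priors of a prior specification
#'
#' @param spec A [prior_spec()].
#' @return A list with elements `A` and `B`, each a [beta_params()] pair, and
#'   attribute `"proper"` (logical) flagging whether both priors are proper
#'   before any data arrive.
#' @export
make_priors <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  pr <- switch(spec$family,
    noninformative = list(A = beta_params(spec$c, spec$c),
                          B = beta_params(spec$c, spec$c)),
    unfavorable_B  = list(A = beta_params(spec$c, 0),
                          B = beta_params(0, spec$c)),
    favorable_B    = list(A = beta_params(0, spec$c),
                          B = beta_params(spec$c, 0)),
    moments        = list(A = prior_from_moments(spec$mean_A, spec$sd),
                          B = prior_from_moments(spec$mean_B, spec$sd)))
  attr(pr, "proper") <- is_proper(pr$A) && is_proper(pr$B)
  pr
}

#' Conjugate beta posterior for binomial response data
#'
#' With a `beta(a, b)` prior on the response rate and `k` responders among
#' `n` patients, the posterior is `beta(a + k, b + n - k)`. The posterior
#' must be proper; improper priors (e.g. Haldane, or the unfavorable /
#' favorable pairs) are accepted provided the data make the posterior proper.
#'
#' @param prior A [beta_params()] pair (possibly improper).
#' @param k Number of responders, `0 <= k <= n`.
#' @param n Number of patients enrolled.
#' @return A proper [beta_params()] pair.
#' @examples
#' posterior_params(beta_params(1, 1), k = 31, n = 38)  # beta(32, 8)
#' @export
posterior_params <- function(prior, k, n) {
  prior <- beta_params(prior[[1]], prior[[2]])
  stopifnot(is.numeric(k), is.numeric(n), length(k) == 1L, length(n) == 1L,
            k == round(k), n == round(n))
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  post <- beta_params(prior[["a"]] + k, prior[["b"]] + n - k)
  if (!is_proper(post))
    stop(sprintf("improper posterior beta(%g, %g): prior beta(%g, %g) with %d/%d needs a + k > 0 and b + n - k > 0",
                 post[["a"]], post[["b"]], prior[["a"]], prior[["b"]], k, n))
  post
}
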