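#' Per-arm efficacy hypothesis
#'
#' Bundles the response-rate hypothesis tested within one treatment arm:
#' `p0` is the highest response rate considered ineffective, `p1` the rate
#' considered promising enough to pursue, with maximum type I error `alpha`
#' (declaring an ineffective treatment promising) and maximum type II error
#' `beta` (discarding a promising treatment).
#'
#' @param p0 Unacceptable response rate, in `[0, 1)`.
#' @param p1 Promising response rate, in `(0, 1]`; must exceed `p0`.
#' @param alpha Maximum type I error rate, in `(0, 1)`. Default 0.10.
#' @param beta Maximum type II error rate, in `(0, 1)`. Default 0.10.
#'
#' @return An object of class `"ptw_hypothesis"`: a list with elements
#'   `p0`, `p1`, `alpha`, `beta`.
#' @examples
#' hypothesis(0.2, 0.4, alpha = 0.1, beta = 0.1)
#' @export
hypothesis <- function(p0, p1, alpha = 0.10, beta = 0.10) {
  stopifnot(is.numeric(p0), is.numeric(p1), is.numeric(alpha), is.numeric(beta),
            length(p0) == 1L, length(p1) == 1L, length(alpha) == 1L,
            length(beta) == 1L)
  if (!(p0 >= 0 && p0 < 1)) stop("'p0' must lie in [0, 1)")
  if (!(p1 > 0 && p1 <= 1)) stop("'p1' must lie in (0, 1]")
  if (p1 <= p0) stop("'p1' must be strictly greater than 'p0'")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (!(beta > 0 && beta < 1)) stop("'beta' must lie in (0, 1)")
  structure(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta),
            class = "ptw_hypothesis")
}

#' @export
print.ptw_hypothesis <- function(x, ...) {
  cat(sprintf("Single-arm hypothesis: p0 = %g vs p1 = %g (alpha = %g, beta = %g)\n",
              x$p0, x$p1, x$alpha, x$beta))
  invisible(x)
}

#' Simon two-stage design
#'
#' Constructs a Simon two-stage single-arm design. `n1` patients are enrolled
#' in the first stage; the arm stops for futility if `r1` or fewer respond.
#' Otherwise `n - n1` additional patients are enrolled, and the treatment is
#' declared ineffective if the total number of responders is `r` or less.
#' An arm whose total responders exceed `r` "passes" the second stage.
#'
#' @param n1 Stage-1 sample size.
#' @param r1 Stage-1 futility bound (stop if responders `<= r1`); `0 <= r1 < n1`.
#' @param n Total sample size; `n > n1`.
#' @param r Final futility bound (ineffective if total responders `<= r`);
#'   `r1 <= r < n`.
#' @param kind Optional label, `"optimal"` or `"minimax"`, recording which
#'   search objective produced the design.
#'
#' @return An object of class `"simon_design"`: a list with elements `n1`,
#'   `r1`, `n2` (`= n - n1`), `n`, `r` and `kind`.
#' @seealso [simon_search()] to find designs satisfying a [hypothesis()].
#' @examples
#' simon_design(17, 3, 37, 10)
#' @export
simon_design <- function(n1, r1, n, r, kind = NULL) {
  vals <- c(n1 = n1, r1 = r1, n = n, r = r)
  if (any(vals != round(vals))) stop("design parameters must be integers")
  if (!(r1 >= 0 && r1 < n1)) stop("need 0 <= r1 < n1")
  if (n <= n1) stop("need n > n1 (at least one stage-2 patient)")
  if (!(r >= r1 && r < n)) stop("need r1 <= r < n")
  structure(list(n1 = as.integer(n1), r1 = as.integer(r1),
                 n2 = as.integer(n - n1), n = as.integer(n),
                 r = as.integer(r), kind = kind),
            class = "simon_design")
}

#' @export
print.simon_design <- function(x, ...) {
  kind <- if (is.null(x$kind)) "" else paste0(" (", x$kind, ")")
  cat(sprintf("Simon two-stage design%s\n", kind))
  cat(sprintf("  Stage 1: enrol %d; stop if <= %d respond\n", x$n1, x$r1))
  cat(sprintf("  Stage 2: enrol %d more (total %d); ineffective if <= %d respond in total\n",
              x$n2, x$n, x$r))
  if (!is.null(x$characteristics)) {
    ch <- x$characteristics
    cat(sprintf("  Attained alpha = %.4f, power = %.4f, PET(p0) = %.4f, EN(p0) = %.2f\n",
                ch$attained_alpha, ch$attained_power, ch$pet0, ch$en0))
  }
  invisible(x)
}

check_rate <- function(p, what = "p") {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (is.na(p) || p < 0 || p > 1) stop(sprintf("'%s' must lie in [0, 1]", what))
  p
}

#' Probability an arm passes both stages
#'
#' Exact probability that a single arm run under a Simon two-stage design
#' clears the stage-1 futility bound and exceeds the final bound, as a
#' function of the true response rate: the sum over stage-1 responder counts
#' `x1 > r1` of the binomial mass at `x1` times the probability that stage-2
#' responders exceed `r - x1`.
#'
#' @param design A [simon_design()].
#' @param p True per-patient response probability, in `[0, 1]`.
#' @return The pass probability, a number in `[0, 1]`.
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' pass_probability(d, 0.2)  # attained type I error of the arm
#' pass_probability(d, 0.4)  # attained power of the arm
#' @export
pass_probability <- function(design, p) {
  stopifnot(inherits(design, "simon_design"))
  check_rate(p)
  x1 <- (design$r1 + 1L):design$n1
  sum(stats::dbinom(x1, design$n1, p) *
        stats::pbinom(design$r - x1, design$n2, p, lower.tail = FALSE))
}

#' Probability an arm stops at stage 1
#'
#' Exact probability of early termination: `r1` or fewer responders among the
#' first `n1` patients.
#'
#' @inheritParams pass_probability
#' @return The early-termination probability.
#' @export
stage1_fail_probability <- function(design, p) {
  stopifnot(inherits(design, "simon_design"))
  check_rate(p)
  stats::pbinom(design$r1, design$n1, p)
}

#' Distribution of total responders among passing outcomes
#'
#' For each achievable total responder count `k` in `(r+1):n`, the joint
#' probability that the arm passes both stages *and* ends with exactly `k`
#' responders. Summing the vector recovers [pass_probability()]. This is the
#' per-arm ingredient for enumerating the joint outcome distribution of a
#' two-arm trial.
#'
#' @inheritParams pass_probability
#' @return A named numeric vector over `k = (r+1):n`; entries are
#'   unconditional probabilities (not renormalised).
#' @examples
#' d <- simon_design(17, 3, 37, 10)
#' pmf <- pass_total_pmf(d, 0.4)
#' sum(pmf) - pass_probability(d, 0.4)  # ~0
#' @export
pass_total_pmf <- function(design, p) {
  stopifnot(inherits(design, "simon_design"))
  check_rate(p)
  ks <- (design$r + 1L):design$n
  out <- vapply(ks, function(k) {
    x1 <- max(design$r1 + 1L, k - design$n2):min(design$n1, k)
    sum(stats::dbinom(x1, design$n1, p) * stats::dbinom(k - x1, design$n2, p))
  }, numeric(1))
  names(out) <- ks
  out
}

#' Exact characteristics of a Simon design under a hypothesis
#'
#' Computes the attained error rates and the classical design summaries:
#' probability of early termination under `p0` (PET) and expected sample
#' size under `p0`, `EN(p0) = n1 + (1 - PET) * n2`.
#'
#' @param design A [simon_design()].
#' @param h A [hypothesis()].
#' @return A list with `attained_alpha` (pass probability at `p0`),
#'   `attained_power` (pass probability at `p1`), `pet0` and `en0`.
#' @export
design_characteristics <- function(design, h) {
  stopifnot(inherits(design, "simon_design"), inherits(h, "ptw_hypothesis"))
  pet0 <- stage1_fail_probability(design, h$p0)
  list(attained_alpha = pass_probability(design, h$p0),
       attained_power = pass_probability(design, h$p1),
       pet0 = pet0,
       en0 = design$n1 + (1 - pet0) * design$n2)
}

#' Search for an optimal or minimax Simon two-stage design
#'
#' Exhaustive search over `(n1, r1, n, r)` with `n <= n_max` for designs whose
#' exact pass probability is at most `alpha` under `p0` and at least
#' `1 - beta` under `p1`. The optimal design minimises the expected sample
#' size under `p0`; the minimax design minimises the maximum sample size `n`,
#' with `EN(p0)` as tie-breaker. Remaining ties are broken deterministically
#' by smallest `n`, then `n1`, then `r1`.
#'
#' @param h A [hypothesis()], or `NULL` to build one from `p0`, `p1`,
#'   `alpha`, `beta`.
#' @param kind `"optimal"` (default) or `"minimax"`.
#' @param n_max Largest total sample size searched. Default 100.
#' @param p0,p1,alpha,beta Convenience scalars used when `h` is `NULL`.
#' @return A [simon_design()] with the attained [design_characteristics()]
#'   stored in `$characteristics` and the generating hypothesis in
#'   `$hypothesis`.
#' @examples
#' simon_search(p0 = 0.2, p1 = 0.4, alpha = 0.1, beta = 0.1)
#' @export
simon_search <- function(h = NULL, kind = c("optimal", "minimax"), n_max = 100,
                         p0, p1, alpha = 0.10, beta = 0.10) {
  kind <- match.arg(kind)
  if (is.null(h)) h <- hypothesis(p0, p1, alpha, beta)
  stopifnot(inherits(h, "ptw_hypothesis"))
  if (n_max < 2) stop("'n_max' must be at least 2")

  best <- NULL
  # objective: (en0) for optimal; (n, en0) for minimax; ties -> n, n1, r1
  better <- function(cand, cur) {
    key_cand <- if (kind == "optimal") {
      c(cand$en0, cand$n, cand$n1, cand$r1)
    } else {
      c(cand$n, cand$en0, cand$n1, cand$r1)
    }
    if (is.null(cur)) return(TRUE)
    key_cur <- if (kind == "optimal") {
      c(cur$en0, cur$n, cur$n1, cur$r1)
    } else {
      c(cur$n, cur$en0, cur$n1, cur$r1)
    }
    d <- key_cand - key_cur
    i <- which(abs(d) > 1e-12)
    length(i) > 0 && d[i[1]] < 0
  }

  for (n1 in seq_len(n_max - 1L)) {
    d0 <- stats::dbinom(0:n1, n1, h$p0)
    d1 <- stats::dbinom(0:n1, n1, h$p1)
    for (r1 in 0:(n1 - 1L)) {
      # stage-1 power is an upper bound on overall power
      if (sum(d1[(r1 + 2L):(n1 + 1L)]) < 1 - h$beta) break
      pet0 <- sum(d0[seq_len(r1 + 1L)])
      x1 <- (r1 + 1L):n1
      q0 <- d0[x1 + 1L]
      q1 <- d1[x1 + 1L]
      for (n2 in seq_len(n_max - n1)) {
        n <- n1 + n2
        en0 <- n1 + (1 - pet0) * n2
        # cheap dominance pruning (exact comparison happens in better())
        if (!is.null(best)) {
          if (kind == "optimal" && en0 > best$en0 + 1e-12) next
          if (kind == "minimax" && n > best$n) break
        }
        # pmf of total responders among stage-1-passing paths
        b0 <- stats::dbinom(0:n2, n2, h$p0)
        b1 <- stats::dbinom(0:n2, n2, h$p1)
        pmf0 <- numeric(n + 1L)
        pmf1 <- numeric(n + 1L)
        for (i in seq_along(x1)) {
          idx <- x1[i] + 0:n2 + 1L
          pmf0[idx] <- pmf0[idx] + q0[i] * b0
          pmf1[idx] <- pmf1[idx] + q1[i] * b1
        }
        tail0 <- rev(cumsum(rev(pmf0)))  # tail0[k+1] = P(K >= k, pass stage 1)
        # smallest r with attained alpha <= alpha maximises power among valid r
        ok <- which(tail0 <= h$alpha) - 2L
        ok <- ok[ok >= r1 & ok < n]
        if (!length(ok)) next
        r <- min(ok)
        tail1 <- rev(cumsum(rev(pmf1)))
        if (tail1[r + 2L] < 1 - h$beta) next
        cand <- list(n1 = n1, r1 = r1, n2 = n2, n = n, r = r, en0 = en0)
        if (better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf("search bound exceeded: no feasible Simon design with n <= %d",
                 n_max))
  }
  out <- simon_design(best$n1, best$r1, best$n, best$r, kind = kind)
  out$hypothesis <- h
  out$characteristics <- design_characteristics(out, h)
  out
}
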