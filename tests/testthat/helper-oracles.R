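# Independent oracles used to pin expected values. These deliberately use
# different formulations from the package internals: raw double summations
# over outcome grids, choose()-based table enumeration, and Monte Carlo.

# the trial design used throughout: Simon optimal for 20% vs 40%, 10%/10%
design37 <- simon_design(17, 3, 37, 10)

# brute-force pass probability: double sum of binomial pmf products
oracle_pass_prob <- function(n1, r1, n2, r, p) {
  total <- 0
  for (x1 in (r1 + 1):n1) {
    for (x2 in 0:n2) {
      if (x1 + x2 > r)
        total <- total + dbinom(x1, n1, p) * dbinom(x2, n2, p)
    }
  }
  total
}

# Monte Carlo of P(X > Y) for independent beta variables
oracle_beta_mc <- function(params_B, params_A, n = 1e6) {
  x <- rbeta(n, params_B[[1]], params_B[[2]])
  y <- rbeta(n, params_A[[1]], params_A[[2]])
  mean(x > y)
}

# one-sided Fisher p by explicit enumeration of all tables with the observed
# margins, using choose() arithmetic only
oracle_fisher_enum <- function(kB, fB, kA, fA) {
  nB <- kB + fB; nA <- kA + fA; m <- kB + kA
  xs <- max(0, m - nA):min(nB, m)
  probs <- choose(nB, xs) * choose(nA, m - xs) / choose(nA + nB, m)
  sum(probs[xs >= kB])
}

# exhaustive Simon design search on the raw (n1, r1, n2, r) grid, computing
# error rates by tabulating the joint (x1, x2) outcome matrix; restricted
# search bound keeps it affordable
oracle_simon_search <- function(p0, p1, alpha, beta, nmax, kind) {
  best <- NULL
  for (n1 in 1:(nmax - 1)) {
    for (n2 in 1:(nmax - n1)) {
      n <- n1 + n2
      P0 <- outer(dbinom(0:n1, n1, p0), dbinom(0:n2, n2, p0))
      P1 <- outer(dbinom(0:n1, n1, p1), dbinom(0:n2, n2, p1))
      K <- outer(0:n1, 0:n2, "+")
      for (r1 in 0:(n1 - 1)) {
        pass1 <- (0:n1) > r1
        if (sum(dbinom(which(pass1) - 1, n1, p1)) < 1 - beta) break
        pet0 <- 1 - sum(dbinom(which(pass1) - 1, n1, p0))
        en0 <- n1 + (1 - pet0) * n2
        m0 <- P0 * pass1   # rows recycled over columns
        m1 <- P1 * pass1
        for (r in r1:(n - 1)) {
          sel <- K > r
          if (sum(m0[sel]) > alpha) next
          if (sum(m1[sel]) < 1 - beta) break
          cand <- list(n1 = n1, r1 = r1, n2 = n2, n = n, r = r, en0 = en0)
          key <- function(z) if (kind == "optimal")
            c(z$en0, z$n, z$n1, z$r1) else c(z$n, z$en0, z$n1, z$r1)
          if (is.null(best)) best <- cand
          else {
            d <- key(cand) - key(best)
            i <- which(abs(d) > 1e-12)
            if (length(i) && d[i[1]] < 0) best <- cand
          }
          break  # larger r only loses power at the same alpha
        }
      }
    }
  }
  best
}

# Monte Carlo of the single-arm two-stage pass event
oracle_pass_mc <- function(design, p, reps = 1e6) {
  x1 <- rbinom(reps, design$n1, p)
  cont <- x1 > design$r1
  k <- x1
  k[cont] <- k[cont] + rbinom(sum(cont), design$n2, p)
  mean(cont & k > design$r)
}
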