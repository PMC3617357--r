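# Fixed-step explicit-Euler oracle for single-cell propagation, independent
# of the package's closed-form path.  Integrates dalpha/dt = k(alpha_p -
# alpha) + beta, c' = alpha, with generation increments when the cycle
# integral crosses the next boundary.
eulerPropagate <- function(state, params, mutationSum, beta, tStop,
                           dt = 1e-4) {
  t <- state[["t"]]; a <- state[["alpha"]]; cc <- state[["c"]]
  s <- state[["s"]]; g <- state[["g"]]
  kp_sat <- params@kpSaturation; kp_rate <- params@kpRate
  kp_lin <- params@kpLinear; a_sc <- params@alphaPScale
  gl <- params@gLimit; kfl <- params@kFloor
  k <- max(kfl, kp_sat * (1 - exp(-kp_rate * g)) + kp_lin * g + mutationSum)
  ap <- a_sc * (gl - g)
  repeat {
    if (t >= tStop)
      return(list(event = "censored", t = tStop, alpha = a, c = cc, g = g))
    a2 <- a + dt * (k * (ap - a) + beta)
    dc <- dt * 0.5 * (a + a2)
    cc2 <- cc + dc
    if (cc2 >= 1) {                       # interpolate the crossing time
      f <- (1 - cc) / dc
      return(list(event = "division", t = t + f * dt,
                  alpha = a + f * (a2 - a), c = 1, g = g))
    }
    if (cc2 <= -1) {
      f <- (-1 - cc) / dc
      return(list(event = "death", t = t + f * dt,
                  alpha = a + f * (a2 - a), c = -1, g = g))
    }
    s <- s - dc
    if (s <= 0) {
      g <- g + 1
      s <- s + 1
      k <- max(kfl, kp_sat * (1 - exp(-kp_rate * g)) + kp_lin * g +
                 mutationSum)
      ap <- a_sc * (gl - g)
    }
    a <- a2; cc <- cc2; t <- t + dt
  }
}

# Random live-cell states spanning the regimes the simulation visits.
randomCellStates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    g = sample(1:20, n, replace = TRUE),
    k = runif(n, 0, 5),
    alpha = runif(n, -2, 15),
    c = runif(n, -0.8, 0.8),
    s = runif(n, 0.05, 1),
    beta = rnorm(n, 5, 0.5))
}

# Random binary lineage trees (parent vectors) with alive leaves.
randomTree <- function(nLeaves, seed) {
  set.seed(seed)
  parent <- c(0L)
  open <- c(1L)                   # nodes that may still receive children
  nkids <- c(0L)
  while (sum(nkids == 0L) < nLeaves) {
    p <- open[sample.int(length(open), 1)]
    i <- length(parent) + 1L
    parent <- c(parent, p)
    nkids <- c(nkids, 0L)
    nkids[p] <- nkids[p] + 1L
    if (nkids[p] == 2L) open <- setdiff(open, p)
    open <- c(open, i)
  }
  leaves <- which(nkids == 0L)
  alive <- rep(FALSE, length(parent))
  alive[leaves] <- runif(length(leaves)) < 0.8
  if (!any(alive)) alive[leaves[1]] <- TRUE
  list(parent = parent, alive = alive)
}

# Brute-force descendant counts: climb to the root from every alive node.
bruteCounts <- function(parent, alive) {
  n <- length(parent)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    j <- i
    while (j != 0L) {
      cnt[j] <- cnt[j] + 1L
      j <- parent[j]
    }
  }
  cnt
}

# Brute-force MRCA(x): deepest node covering ceil(x * mass), ties toward
# larger count then lexicographically smaller code.
bruteMrca <- function(tree, x) {
  cnt <- bruteCounts(tree@parent, tree@alive)
  m <- ceiling(x * cnt[1])
  cand <- which(cnt >= m)
  cand <- cand[tree@d[cand] == max(tree@d[cand])]
  cand <- cand[cnt[cand] == max(cnt[cand])]
  if (length(cand) > 1)
    cand <- cand[order(lineageCode(tree, cand))][1]
  cand[1]
}


# |Delta c| between the closed form and the Euler oracle, evaluated at the
# earlier of the two event times (at that instant one path sits exactly at
# +-1); for two censored runs, the difference of the censored c values.
oracleDeviation <- function(state, params, msum, beta, tStop, cf, eu) {
  if (cf$event == "censored" && eu$event == "censored")
    return(abs(cf$c - eu$c))
  if (cf$t <= eu$t) {
    other <- eulerPropagate(state, params, msum, beta, tStop = cf$t)
    abs(other$c - cf$c)
  } else {
    other <- propagateCell(state, params, mutationSum = msum, beta = beta,
                           tStop = eu$t)
    abs(other$c - eu$c)
  }
}


# Deviation with oracle refinement: the explicit-Euler oracle at
# dt = 1e-4 carries O(dt) truncation drift on rare months-long
# near-critical trajectories; where the apparent deviation is not clearly
# inside tolerance, re-run the oracle at a finer step before judging.
oracleDeviationRefined <- function(state, params, msum, beta, tStop,
                                   cf, eu) {
  dev <- oracleDeviation(state, params, msum, beta, tStop, cf, eu)
  if (dev <= 8e-4) return(dev)
  eu2 <- eulerPropagate(state, params, msum, beta, tStop = tStop,
                        dt = 1e-5)
  oracleDeviation(state, params, msum, beta, tStop, cf, eu2)
}
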