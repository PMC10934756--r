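# Independent oracles: deliberately plain, loop-based re-derivations of the
# quantities the production code computes, sharing no code path with it.

# Scalar trapezoid, written pointwise with explicit branches.
oracleTrap <- function(x, p) {
  if (x < p[1] || x > p[4]) return(0)
  if (x >= p[2] && x <= p[3]) return(1)
  if (x < p[2]) {
    if (p[2] == p[1]) return(1)
    return((x - p[1]) / (p[2] - p[1]))
  }
  if (p[4] == p[3]) return(1)
  (p[4] - x) / (p[4] - p[3])
}

# Dense-sampling Mamdani evaluator: pointwise min/max over a fine output
# grid, with the majority rule base written out by nested loops.
oracleMamdaniCrisp <- function(scores,
                               inputL = c(0, 0, 0.5, 0.9),
                               inputH = c(0.1, 0.5, 1, 1),
                               outputDR = c(0, 0, 0.3, 0.5),
                               outputAL = c(0.5, 0.7, 1, 1),
                               nGrid = 1001L) {
  u <- seq(0, 1, length.out = nGrid)
  agg <- rep(0, nGrid)
  for (a1 in c("L", "H")) for (a2 in c("L", "H")) for (a3 in c("L", "H")) {
    terms <- c(a1, a2, a3)
    fire <- 1
    for (i in 1:3) {
      p <- if (terms[i] == "L") inputL else inputH
      d <- oracleTrap(scores[i], p)
      if (d < fire) fire <- d
    }
    out <- if (sum(terms == "L") >= 2) outputDR else outputAL
    for (g in seq_len(nGrid)) {
      clipped <- min(fire, oracleTrap(u[g], out))
      if (clipped > agg[g]) agg[g] <- clipped
    }
  }
  sum(u * agg) / sum(agg)
}

# Frame-by-frame segmentation oracle: walk the series and open/close
# intervals by hand.
oracleSegments <- function(values, threshold) {
  starts <- integer(); ends <- integer()
  inRun <- FALSE
  for (i in seq_along(values)) {
    closed <- values[i] < threshold
    if (closed && !inRun) { starts <- c(starts, i - 1L); inRun <- TRUE }
    if (!closed && inRun) { ends <- c(ends, i - 1L); inRun <- FALSE }
  }
  if (inRun) ends <- c(ends, length(values))
  data.frame(start = starts, end = ends)
}

# Exhaustive maximum disjoint-triple matcher for the blink signature:
# branch over every feasible (EOG1, EOG2, EOG3) candidate assignment.
oracleMaxTriples <- function(t1, t2, t3, tol) {
  best <- 0L
  recurse <- function(i, used2, used3, count) {
    if (count + (length(t1) - i + 1L) <= best) return()
    if (i > length(t1)) { best <<- max(best, count); return() }
    recurse(i + 1L, used2, used3, count)  # skip this anchor
    for (j in seq_along(t2)) {
      if (used2[j] || abs(t2[j] - t1[i]) > tol) next
      for (k in seq_along(t3)) {
        if (used3[k] || abs(t3[k] - t1[i]) > tol ||
            abs(t3[k] - t2[j]) > tol) next
        used2[j] <- TRUE; used3[k] <- TRUE
        recurse(i + 1L, used2, used3, count + 1L)
        used2[j] <- FALSE; used3[k] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(t2)), rep(FALSE, length(t3)), 0L)
  best
}

# Direct (single-segment, boxcar) periodogram for PSD cross-checks.
oraclePeriodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  spec <- abs(stats::fft(x))^2 / (fs * n)
  nfreq <- n %/% 2L + 1L
  half <- spec[seq_len(nfreq)]
  lastDouble <- nfreq - if (n %% 2L == 0L) 1L else 0L
  half[2:lastDouble] <- 2 * half[2:lastDouble]
  list(freq = (seq_len(nfreq) - 1L) * fs / n, psd = half)
}

# Shared fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fixtureCorpus <- function() fixture("corpus", genEyeCorpus(100, seed = 42))
fixtureSplit <- function() fixture("split", splitEyeCorpus(fixtureCorpus(), 70))
fixtureMlp <- function()
  fixture("mlp", trainEyeStateMLP(fixtureSplit()$train, seed = 1))
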