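test_that("trapezoid membership honors endpoints and symmetry", {
  sys <- fuzzySystem()
  expect_equal(membershipDegree(sys, 1, "L", 0), 1)
  expect_equal(membershipDegree(sys, 1, "L", 1), 0)
  expect_equal(membershipDegree(sys, 1, "H", 0), 0)
  expect_equal(membershipDegree(sys, 1, "H", 1), 1)
  expect_equal(membershipDegree(sys, 2, "L", 0.5),
               membershipDegree(sys, 2, "H", 0.5))
  expect_error(trapezoidMf(1.2, c(0, 0, 0.5, 1)), "outside")
})

test_that("the rule base covers all corners with the >=2-low majority rule", {
  rb <- buildRuleBase()
  expect_equal(nrow(rb), 8)
  expect_equal(anyDuplicated(rb[, 1:3]), 0)
  lookup <- function(a, b, c)
    rb$out[rb$in1 == a & rb$in2 == b & rb$in3 == c]
  # the four tabulated decisions
  expect_equal(lookup("L", "L", "L"), "DR")
  expect_equal(lookup("L", "L", "H"), "DR")
  expect_equal(lookup("L", "H", "H"), "AL")
  expect_equal(lookup("H", "H", "H"), "AL")
  # majority completion on a corner not tabulated
  expect_equal(lookup("H", "L", "L"), "DR")
  for (i in seq_len(8)) {
    nLow <- sum(rb[i, 1:3] == "L")
    expect_equal(rb$out[i], if (nLow >= 2) "DR" else "AL")
  }
})

test_that("inference clips and aggregates correctly at the corners", {
  sys <- fuzzySystem()
  curveD <- fuzzyInfer(sys, c(0, 0, 0))
  # only the (L,L,L)->DR rule fires (at 1): the aggregate IS the DR trapezoid
  expect_equal(curveD$degree, trapezoidMf(curveD$grid, c(0, 0, 0.3, 0.5)))
  curveA <- fuzzyInfer(sys, c(1, 1, 1))
  expect_equal(curveA$degree, trapezoidMf(curveA$grid, c(0.5, 0.7, 1, 1)))
  expect_true(all(curveD$degree >= 0 & curveD$degree <= 1))
  expect_error(fuzzyInfer(sys, c(0.5, 1.2, 0)), "\\[0, 1\\]")
})

test_that("centroid defuzzification reduces known shapes exactly", {
  g <- seq(0, 1, length.out = 2001)
  # symmetric curve about 0.5
  expect_equal(defuzzifyCentroid(list(grid = g,
                                      degree = exp(-((g - 0.5) / 0.1)^2))),
               0.5, tolerance = 1e-9)
  # symmetric triangle peaked at 0.2
  tri <- pmax(0, 1 - abs(g - 0.2) / 0.1)
  expect_equal(defuzzifyCentroid(list(grid = g, degree = tri)), 0.2,
               tolerance = 1e-6)
  # rectangle over [0.6, 1.0]
  rect <- as.numeric(g >= 0.6 & g <= 1.0)
  expect_equal(defuzzifyCentroid(list(grid = g, degree = rect)), 0.8,
               tolerance = 1e-3)
  expect_error(defuzzifyCentroid(list(grid = g, degree = rep(0, 2001))),
               "zero-area")
})

test_that("corner decisions reproduce the rule base and the dense oracle", {
  sys <- fuzzySystem()
  rb <- buildRuleBase()
  corners <- expand.grid(s1 = c(0, 1), s2 = c(0, 1), s3 = c(0, 1))
  for (i in seq_len(nrow(corners))) {
    s <- as.numeric(corners[i, ])
    dec <- fuzzyDecide(sys, s)
    terms <- ifelse(s == 0, "L", "H")
    want <- rb$out[rb$in1 == terms[1] & rb$in2 == terms[2] &
                     rb$in3 == terms[3]]
    expect_equal(dec$label, if (want == "DR") "DROWSY" else "ALERT",
                 info = paste(s, collapse = ","))
    expect_lt(abs(dec$crisp - oracleMamdaniCrisp(s)), 1e-3)
  }
  # tabulated rows by name
  expect_equal(fuzzyDecide(sys, c(0, 0, 1))$label, "DROWSY")
  expect_equal(fuzzyDecide(sys, c(1, 1, 1))$label, "ALERT")
})

test_that("production inference agrees with the dense oracle off the corners", {
  sys <- fuzzySystem(gridN = 1001L)
  set.seed(55)
  for (rep in 1:40) {
    s <- stats::runif(3)
    expect_lt(abs(fuzzyDecide(sys, s)$crisp - oracleMamdaniCrisp(s)), 1e-3)
  }
})

test_that("the midpoint is the documented tie-break (ALERT at exactly 0.5)", {
  dec <- fuzzyDecide(fuzzySystem(), c(0.5, 0.5, 0.5))
  expect_equal(dec$crisp, 0.5, tolerance = 1e-9)
  expect_equal(dec$label, "ALERT")
})

test_that("crisp output is monotone and permutation-symmetric", {
  sys <- fuzzySystem()
  ax <- seq(0, 1, length.out = 21)
  # full 21^3 grid
  vals <- array(NA_real_, c(21, 21, 21))
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    vals[i, j, k] <- defuzzifyCentroid(fuzzyInfer(sys, c(ax[i], ax[j], ax[k])))
  eps <- 1e-9
  expect_true(all(apply(vals, c(2, 3), diff) >= -eps))
  expect_true(all(apply(vals, c(1, 3), diff) >= -eps))
  expect_true(all(apply(vals, c(1, 2), diff) >= -eps))
  # permutation symmetry of the majority system
  set.seed(56)
  for (rep in 1:15) {
    s <- stats::runif(3)
    ref <- defuzzifyCentroid(fuzzyInfer(sys, s))
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (p in perms)
      expect_equal(defuzzifyCentroid(fuzzyInfer(sys, s[p])), ref,
                   tolerance = 1e-9)
  }
})

test_that("the decision surface matches the rule base at its corners", {
  sys <- fuzzySystem()
  surf <- decisionSurface(sys, resolution = 2L, fixedInput = 3L,
                          fixedValue = 1)
  # varied inputs 1 and 2, input 3 held High
  getC <- function(x, y) surf$crisp[surf$x == x & surf$y == y]
  expect_lt(getC(0, 0), 0.5)  # (L,L,H) -> DR
  expect_gt(getC(1, 1), 0.5)  # (H,H,H) -> AL
  expect_gt(getC(0, 1), 0.5)  # (L,H,H) -> AL
  expect_gt(getC(1, 0), 0.5)  # (H,L,H) -> AL
  full <- decisionSurface(sys, resolution = 11L)
  expect_true(all(full$crisp >= 0 & full$crisp <= 1))
  # monotone along each axis at default MFs
  for (yv in unique(full$y)) {
    row <- full$crisp[full$y == yv][order(full$x[full$y == yv])]
    expect_true(all(diff(row) >= -1e-9))
  }
  expect_error(decisionSurface(sys, resolution = 1L), "at least 2")
})
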