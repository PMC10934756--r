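# Mamdani fuzzy fusion of the three drowsiness channel scores.
#
# Inputs are unit-interval scores from the EEG-or-EOG channel, the
# face-recognition classifier, and the EAR metric (high = alert evidence).
# Each input carries Low/High trapezoids, the output carries DR (drowsy) and
# AL (alert) trapezoids, and the rule base is the majority rule: the driver
# is drowsy when at least two of the three inputs are Low. Inference is the
# standard Mamdani stack — AND = min, implication = clip, aggregation = max,
# centroid defuzzification.

#' Trapezoidal membership degree
#'
#' Piecewise-linear trapezoid with breakpoints a <= b <= c <= d: 0 outside
#' [a, d], 1 on [b, c], linear in between. Degenerate edges (a = b or
#' c = d) give crisp shoulders.
#'
#' @param x evaluation points in [0, 1].
#' @param trap numeric(4) breakpoints.
#' @return membership degrees in [0, 1].
#' @export
trapezoidMf <- function(x, trap) {
  if (any(x < 0 | x > 1)) stop("membership input outside [0, 1]")
  a <- trap[1]; b <- trap[2]; cc <- trap[3]; d <- trap[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
  down <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= d)
  pmax(0, pmin(up, down, 1))
}

#' The 8-rule majority rule base
#'
#' All eight L/H corners of the three inputs, with consequent DR when at
#' least two antecedent terms are L (closed-eye evidence on a majority of
#' channels) and AL otherwise. The four explicitly tabulated decisions —
#' (L,L,L) drowsy, (L,L,H) drowsy, (L,H,H) alert, (H,H,H) alert — appear
#' verbatim; the remaining corners follow from the same majority sentence.
#'
#' @return data.frame with columns in1, in2, in3 ("L"/"H") and out
#'   ("DR"/"AL").
#' @export
buildRuleBase <- function() {
  g <- expand.grid(in1 = c("L", "H"), in2 = c("L", "H"), in3 = c("L", "H"),
                   stringsAsFactors = FALSE)
  nLow <- rowSums(g == "L")
  g$out <- ifelse(nLow >= 2, "DR", "AL")
  g
}

#' Construct the fuzzy fusion system
#'
#' Default membership functions are symmetric — input L = (0, 0, 0.5, 0.9)
#' and H = (0.1, 0.5, 1, 1) mirror each other, as do output DR =
#' (0, 0, 0.3, 0.5) and AL = (0.5, 0.7, 1, 1) — so the corner decisions are
#' forced by the rule base alone and the system is invariant under
#' permutation of its inputs. The input plateaus meet at 0.5, so every score
#' is a full member of at least one term (max(L, H) = 1 everywhere); with a
#' majority rule base this makes the crisp output exactly monotone in each
#' input, where narrower overlaps leave non-monotone ripples mid-range. All
#' breakpoints are configurable.
#'
#' @param inputL,inputH trapezoid breakpoints used for every input's L/H
#'   terms (numeric(4)).
#' @param outputDR,outputAL output trapezoids.
#' @param rules rule base data.frame (default \code{\link{buildRuleBase}()}).
#' @param gridN output-domain discretization (default 501 points).
#' @param decisionThreshold crisp values strictly below it are DROWSY
#'   (default 0.5; a tie is ALERT).
#' @return a \linkS4class{FuzzySystem}.
#' @export
fuzzySystem <- function(inputL = c(0, 0, 0.5, 0.9),
                        inputH = c(0.1, 0.5, 1, 1),
                        outputDR = c(0, 0, 0.3, 0.5),
                        outputAL = c(0.5, 0.7, 1, 1),
                        rules = buildRuleBase(), gridN = 501L,
                        decisionThreshold = 0.5) {
  new("FuzzySystem",
      inputMf = rep(list(list(L = inputL, H = inputH)), 3L),
      outputMf = list(DR = outputDR, AL = outputAL),
      rules = rules, gridN = as.integer(gridN),
      decisionThreshold = decisionThreshold)
}

#' Membership degree of a score in one input term
#'
#' @param sys a \linkS4class{FuzzySystem}.
#' @param input input index 1..3.
#' @param term "L" or "H".
#' @param x score in [0, 1].
#' @return degree in [0, 1].
#' @export
membershipDegree <- function(sys, input, term, x) {
  stopifnot(is(sys, "FuzzySystem"))
  trapezoidMf(x, sys@inputMf[[input]][[term]])
}

#' Mamdani inference: aggregated output membership curve
#'
#' For each rule the firing strength is the min of its three antecedent
#' degrees; the consequent trapezoid is clipped at that strength; the
#' aggregate is the pointwise max over all rules, evaluated on a uniform
#' grid over [0, 1].
#'
#' @param sys a \linkS4class{FuzzySystem}.
#' @param scores numeric(3) channel scores in [0, 1].
#' @return list with \code{grid} (x values) and \code{degree} (aggregated
#'   membership in [0, 1]).
#' @export
fuzzyInfer <- function(sys, scores) {
  stopifnot(is(sys, "FuzzySystem"))
  if (length(scores) != 3L || any(!is.finite(scores)) ||
      any(scores < 0 | scores > 1))
    stop("scores must be three values in [0, 1]")
  grid <- seq(0, 1, length.out = sys@gridN)
  deg <- lapply(1:3, function(i) c(
    L = trapezoidMf(scores[i], sys@inputMf[[i]]$L),
    H = trapezoidMf(scores[i], sys@inputMf[[i]]$H)))
  outCurves <- lapply(sys@outputMf, function(trap) trapezoidMf(grid, trap))
  agg <- numeric(sys@gridN)
  for (r in seq_len(nrow(sys@rules))) {
    fire <- min(deg[[1]][sys@rules$in1[r]], deg[[2]][sys@rules$in2[r]],
                deg[[3]][sys@rules$in3[r]])
    if (fire > 0)
      agg <- pmax(agg, pmin(fire, outCurves[[sys@rules$out[r]]]))
  }
  list(grid = grid, degree = agg)
}

#' Centroid defuzzification
#'
#' Area centroid of the aggregated membership curve by trapezoidal
#' integration. A zero-area curve (impossible with a complete rule base and
#' overlapping input terms) is an error.
#'
#' @param curve list with \code{grid} and \code{degree}, as returned by
#'   \code{\link{fuzzyInfer}}.
#' @return crisp value in [0, 1].
#' @export
defuzzifyCentroid <- function(curve) {
  x <- curve$grid; y <- curve$degree
  dx <- diff(x)
  area <- sum((y[-1] + y[-length(y)]) / 2 * dx)
  if (area <= 0) stop("zero-area membership curve: no rule fired")
  moment <- sum((x[-1] * y[-1] + x[-length(x)] * y[-length(y)]) / 2 * dx)
  moment / area
}

#' Fuse three channel scores into a drowsy/alert decision
#'
#' Runs Mamdani inference and centroid defuzzification; the label is DROWSY
#' when the crisp value falls strictly below the decision threshold (a value
#' exactly at the threshold is ALERT). At all eight binary corners the label
#' reproduces the rule-base consequent.
#'
#' @inheritParams fuzzyInfer
#' @return list with \code{scores}, \code{crisp} in [0, 1], and \code{label}
#'   ("DROWSY"/"ALERT").
#' @examples
#' sys <- fuzzySystem()
#' fuzzyDecide(sys, c(0, 0, 1))$label  # two low inputs: DROWSY
#' @export
fuzzyDecide <- function(sys, scores) {
  crisp <- defuzzifyCentroid(fuzzyInfer(sys, scores))
  list(scores = as.numeric(scores), crisp = crisp,
       label = if (crisp < sys@decisionThreshold) "DROWSY" else "ALERT")
}

#' Crisp decision surface over two inputs
#'
#' Evaluates the crisp fused output on a uniform 2-D grid of two inputs with
#' the third held fixed — the standard qualitative view of a fuzzy
#' controller.
#'
#' @param sys a \linkS4class{FuzzySystem}.
#' @param resolution grid points per axis, >= 2 (default 21).
#' @param fixedInput which input (1..3) to hold fixed.
#' @param fixedValue its value in [0, 1].
#' @return data.frame with the two varied scores (\code{x}, \code{y}) and
#'   \code{crisp}.
#' @export
decisionSurface <- function(sys, resolution = 21L, fixedInput = 3L,
                            fixedValue = 1) {
  if (resolution < 2L) stop("resolution must be at least 2")
  ax <- seq(0, 1, length.out = resolution)
  vary <- setdiff(1:3, fixedInput)
  g <- expand.grid(x = ax, y = ax)
  g$crisp <- vapply(seq_len(nrow(g)), function(i) {
    s <- numeric(3)
    s[vary] <- c(g$x[i], g$y[i])
    s[fixedInput] <- fixedValue
    defuzzifyCentroid(fuzzyInfer(sys, s))
  }, numeric(1))
  g
}
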