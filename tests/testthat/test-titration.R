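# CSP computation, peak matching, interface calling and Kd fitting.

test_that("computeCsp evaluates the weighted-distance formula", {
  p <- function(res, h, n) list(residue = res, deltaH = h, deltaN = n)
  expect_equal(computeCsp(p(1, 8.2, 120), p(1, 8.2, 120)), 0)
  # hand evaluation: sqrt(0.1^2 + (0.5/5)^2) = sqrt(0.02)
  expect_equal(computeCsp(p(1, 8.0, 120.0), p(1, 8.1, 120.5)),
               0.1414214, tolerance = 1e-6)
  # nitrogen-only shift of 1 ppm scales to 0.2
  expect_equal(computeCsp(p(1, 8.0, 120.0), p(1, 8.0, 121.0)), 0.2)
  # symmetric and sign-flip invariant
  a <- p(1, 8.03, 119.2); b <- p(1, 7.91, 120.4)
  expect_equal(computeCsp(a, b), computeCsp(b, a))
  expect_error(computeCsp(p(1, 8, 120), p(2, 8, 120)), "pairing")
})

test_that("matchPeaks maps identical lists onto themselves", {
  ref <- data.frame(residue = c(3L, 8L, 15L),
                    deltaH = c(7.9, 8.4, 8.9),
                    deltaN = c(110, 118, 126))
  m <- matchPeaks(ref, ref)
  expect_equal(m$matches$residue, ref$residue)
  expect_equal(m$matches$otherIndex, seq_len(3))
  expect_length(m$broadened, 0)
})

test_that("matchPeaks reports deleted residues as broadened", {
  ref <- data.frame(residue = c(3L, 8L, 15L),
                    deltaH = c(7.9, 8.4, 8.9), deltaN = c(110, 118, 126))
  other <- ref[-2, ]
  m <- matchPeaks(ref, other)
  expect_equal(m$broadened, 8L)
  expect_equal(m$matches$residue, c(3L, 15L))
})

test_that("matchPeaks picks the nearer candidate, ties to lower residue id", {
  ref <- data.frame(residue = 1L, deltaH = 8.0, deltaN = 120)
  two <- data.frame(residue = c(5L, 9L),
                    deltaH = c(8.02, 8.05), deltaN = c(120, 120))
  m <- matchPeaks(ref, two)
  expect_equal(m$matches$otherIndex, 1) # nearer
  tie <- data.frame(residue = c(9L, 5L),
                    deltaH = c(8.125, 7.875), deltaN = c(120, 120))
  expect_warning(m2 <- matchPeaks(ref, tie), "tie")
  expect_equal(tie$residue[m2$matches$otherIndex], 5L)
})

test_that("matchPeaks raises an ambiguity error naming both claimants", {
  ref <- data.frame(residue = c(1L, 2L),
                    deltaH = c(8.00, 8.01), deltaN = c(120, 120))
  one <- data.frame(residue = 7L, deltaH = 8.005, deltaN = 120)
  expect_error(matchPeaks(ref, one), "1\\+2")
})

test_that("matchPeaks agrees with the exhaustive assignment oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    ref <- data.frame(residue = seq_len(n),
                      # spaced > 2x the gate so matching is unambiguous
                      deltaH = 7.5 + 0.4 * seq_len(n) + runif(n, 0, 0.05),
                      deltaN = runif(n, 108, 128))
    # displace each peak slightly, shuffle, drop one at random
    other <- ref
    other$deltaH <- other$deltaH + runif(n, -0.02, 0.02)
    other$deltaN <- other$deltaN + runif(n, -0.1, 0.1)
    drop <- sample(n, 1)
    other <- other[sample(setdiff(seq_len(n), drop)), ]
    rownames(other) <- NULL
    m <- matchPeaks(ref, other)
    om <- oracleMatch(ref, other)
    got <- rep(NA_integer_, n)
    got[match(m$matches$residue, ref$residue)] <- m$matches$otherIndex
    expect_equal(got, as.integer(om))
    expect_equal(m$broadened, ref$residue[drop])
  }
})

test_that("cspProfile recovers the generator closed form", {
  d <- noiselessDesign(kd = 31)
  ts <- simulateTitration(d)
  prof <- cspProfile(ts)
  fb <- boundFraction(50, 5 * 50, 31)
  expected <- fb * sqrt(d@interface$dHmax^2 + (d@interface$dNmax / 5)^2)
  expect_equal(prof$csp[match(d@interface$residue, prof$residue)], expected,
               tolerance = 1e-10)
  expect_false(any(prof$broadened))
})

test_that("cspProfile flags endpoint-broadened residues without a number", {
  d <- titrationDesign(trueKd = 10, broadened = 41L, broadenCutoff = 0.5)
  prof <- cspProfile(simulateTitration(d))
  r <- prof[prof$residue == 41, ]
  expect_true(r$broadened)
  expect_true(is.na(r$csp))
})

test_that("cspProfile requires a ligand-free reference point", {
  ts <- simulateTitration(noiselessDesign())
  broken <- new("TitrationSeries", peaks = ts@peaks,
                proteinTotal = ts@proteinTotal,
                ligandTotal = ts@ligandTotal + 1)
  expect_error(cspProfile(broken), "ligand-free")
})

test_that("callInterface applies mean + 2 SD with strict inequality", {
  rec <- function(csp)
    data.frame(residue = seq_along(csp), csp = csp,
               broadened = rep(FALSE, length(csp)))
  # all equal: SD 0, threshold = mean, strict '>' gives empty interface
  flat <- rec(rep(0.1, 5))
  call <- callInterface(flat)
  expect_equal(call@threshold, 0.1)
  expect_length(call@interfaceResidues, 0)
  # {0,0,0,0,1}: mean 0.2, population SD 0.4, threshold exactly 1.0
  r5 <- rec(c(0, 0, 0, 0, 1))
  call5 <- callInterface(r5)
  expect_equal(call5@mean, 0.2)
  expect_equal(call5@sd, 0.4)
  expect_equal(call5@threshold, 1.0)
  expect_length(call5@interfaceResidues, 0) # 1 is not > 1
  # sample SD flavour is configurable
  expect_equal(callInterface(r5, sdType = "sample")@sd, sd(c(0, 0, 0, 0, 1)))
})

test_that("callInterface excludes broadened records from the statistics", {
  rec <- data.frame(residue = 1:5,
                    csp = c(0.05, 0.05, 0.05, NA, 0.5),
                    broadened = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  call <- callInterface(rec)
  expect_equal(call@excludedBroadened, 4L)
  expect_equal(call@mean, mean(c(0.05, 0.05, 0.05, 0.5)))
  # order invariance
  perm <- rec[c(4, 2, 5, 1, 3), ]
  call2 <- callInterface(perm)
  expect_equal(call2@threshold, call@threshold)
  expect_equal(call2@interfaceResidues, call@interfaceResidues)
  # degenerate input
  allb <- data.frame(residue = 1:3, csp = NA_real_, broadened = TRUE)
  expect_error(callInterface(allb), "degenerate")
})

test_that("predictCsp matches its closed form and limits", {
  expect_equal(predictCsp(50, 0, 31, 0.2), 0)
  # stoichiometric limit: kd -> 0 at lt = pt saturates
  expect_equal(predictCsp(50, 50, 1e-12, 0.2), 0.2, tolerance = 1e-6)
  expect_equal(predictCsp(50, 50, 50, 0.2), 0.0763932, tolerance = 1e-6)
  expect_error(predictCsp(0, 10, 31, 0.2), "pt")
})

test_that("predictCsp agrees with the numerical equilibrium solver", {
  pts <- 10^seq(0, 3, length.out = 10)
  lts <- 10^seq(-1, 3.5, length.out = 10)
  kds <- 10^seq(-1, 4, length.out = 10)
  worst <- 0
  for (pt in pts) for (lt in lts) for (kd in kds) {
    a <- boundFraction(pt, lt, kd)
    b <- oracleBoundFraction(pt, lt, kd)
    worst <- max(worst, abs(a - b) / max(b, 1e-300))
  }
  expect_lt(worst, 1e-10)
})

test_that("predictCsp is increasing in lt and decreasing in kd", {
  lt <- seq(1, 400, length.out = 60)
  v <- predictCsp(50, lt, 31, 0.2)
  expect_true(all(diff(v) > 0))
  kd <- seq(0.5, 500, length.out = 60)
  v2 <- predictCsp(50, 100, kd, 0.2)
  expect_true(all(diff(v2) < 0))
})

test_that("fitKd recovers the generating Kd from noiseless data", {
  ts <- simulateTitration(noiselessDesign(kd = 31))
  fit <- fitKd(ts, residues = 40:44, nBoot = 20, seed = 1)
  expect_equal(kdValue(fit), 31, tolerance = 1e-4)
  expect_equal(unname(cspMax(fit)),
               sqrt(c(0.12, 0.20, 0.25, 0.18, 0.10)^2 +
                      (c(0.60, 1.00, 1.30, 0.80, 0.50) / 5)^2),
               tolerance = 1e-4)
  expect_length(fit@residuals, 5 * 5) # (points - 1) x residues
})

test_that("fitKd bias vanishes as noise shrinks", {
  noise <- c(0.01, 0.002, 4e-4)
  bias <- vapply(noise, function(s) {
    kds <- vapply(1:10, function(seed) {
      ts <- simulateTitration(titrationDesign(noiseSd = s, seed = seed))
      kdValue(fitKd(ts, residues = 40:44, nBoot = 2, seed = seed))
    }, 0)
    abs(mean(kds) - 31) / 31
  }, 0)
  expect_lt(bias[3], 0.01)
  expect_lt(bias[3], bias[1])
})

test_that("per-residue fits of a shared-Kd system agree within uncertainty", {
  ts <- simulateTitration(titrationDesign(noiseSd = 0.002, seed = 21))
  fit <- fitKd(ts, residues = c(41L, 42L), mode = "per-residue",
               nBoot = 200, seed = 5)
  k <- kdValue(fit)
  joint <- sqrt(sum(fit@kdStderr^2))
  expect_lt(abs(k[1] - k[2]), 3 * joint)
})

test_that("fitKd validates its inputs", {
  ts <- simulateTitration(noiselessDesign(ratios = c(0, 5)))
  expect_error(fitKd(ts, residues = 40:44), "underdetermined")
  tsb <- simulateTitration(titrationDesign(trueKd = 10, broadened = 42L,
                                           broadenCutoff = 0.4))
  expect_error(fitKd(tsb, residues = 40:44), "non-broadened")
})

test_that("automatic residue selection fits interface residues only", {
  ts <- simulateTitration(noiselessDesign(kd = 31))
  fit <- fitKd(ts, nBoot = 10, seed = 2)
  expect_true(all(as.integer(names(cspMax(fit))) %in% 40:44))
  expect_equal(kdValue(fit), 31, tolerance = 1e-4)
})
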