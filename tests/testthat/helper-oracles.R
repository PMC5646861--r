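# Independent oracles used to validate the package implementations.
# Each deliberately takes the slow, brute-force route.

# Bound fraction by numerically solving the equilibrium PL = P*L/Kd with
# mass balance pt = P + PL, lt = L + PL (no closed form used).
oracleBoundFraction <- function(pt, lt, kd) {
  if (lt == 0) return(0)
  f <- function(pl) (pt - pl) * (lt - pl) / kd - pl
  pl <- uniroot(f, c(0, min(pt, lt)), tol = 1e-12)$root
  # polish to machine precision with Newton steps
  for (k in 1:50) {
    fp <- (2 * pl - pt - lt) / kd - 1
    step <- f(pl) / fp
    pl <- pl - step
    if (abs(step) < 1e-16 * max(pl, 1e-300)) break
  }
  pl / pt
}

# Mono-exponential fit by dense grid over T with the amplitude solved
# linearly, then golden-section refinement.
oracleDecayFit <- function(delays, intensities) {
  sse <- function(T) {
    e <- exp(-delays / T)
    i0 <- sum(intensities * e) / sum(e^2)
    sum((intensities - i0 * e)^2)
  }
  grid <- exp(seq(log(min(delays[delays > 0]) / 10),
                  log(max(delays) * 10), length.out = 400))
  best <- grid[which.min(vapply(grid, sse, 0))]
  opt <- optimize(sse, best * c(0.5, 2), tol = 1e-12)
  e <- exp(-delays / opt$minimum)
  list(T = opt$minimum, I0 = sum(intensities * e) / sum(e^2))
}

# Superposition by a coarse Euler-angle grid followed by Nelder-Mead
# refinement; translation is optimal (centroid match) for any rotation.
oracleSuperposeRmsd <- function(moving, fixed, gridStep = 15) {
  A <- sweep(moving, 2, colMeans(moving))
  B <- sweep(fixed, 2, colMeans(fixed))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  step <- gridStep * pi / 180
  angles <- seq(0, 2 * pi - step / 2, by = step)
  half <- seq(-pi / 2, pi / 2, by = step)
  best <- NULL; bestV <- Inf
  for (a in angles) for (b in half) for (c in angles) {
    v <- obj(c(a, b, c))
    if (v < bestV) { bestV <- v; best <- c(a, b, c) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Exhaustive window scans for the motif definitions.
oracleConsensusScan <- function(seq, psi = c("L", "I", "V")) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- integer()
  if (n >= 4)
    for (s in 1:(n - 3))
      if (ch[s] %in% psi && ch[s + 1] == "K" && ch[s + 3] == "E")
        out <- c(out, s)
  out
}

oracleSimCores <- function(seq, minCore = 3, minFlank = 2, fw = 4) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- integer()
  if (n >= 4)
    for (s in 1:(n - 3)) {
      core <- sum(ch[s:(s + 3)] %in% c("V", "I", "L"))
      fl <- c(if (s > 1) max(1, s - fw):(s - 1),
              if (s + 4 <= n) (s + 4):min(n, s + 3 + fw))
      if (core >= minCore && sum(ch[fl] %in% c("D", "E", "S")) >= minFlank)
        out <- c(out, s)
    }
  out
}

# Brute-force global alignment score with affine gaps: enumerate every
# alignment (op strings over M/I/D with no I<->D adjacency constraint
# relaxed: all interleavings are allowed) and score it directly. A gap run
# of length L costs open + L * ext.
oracleAlignScore <- function(a, b, sub, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, lastOp) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + sub[ca[i], cb[j]], "M")
    if (i <= length(ca))
      rec(i + 1, j, score - ext - if (lastOp != "D") open else 0, "D")
    if (j <= length(cb))
      rec(i, j + 1, score - ext - if (lastOp != "I") open else 0, "I")
  }
  rec(1, 1, 0, "start")
  best
}

# Exhaustive peak assignment: over all injective mappings from reference
# peaks to candidate peaks within the gate (unmatched allowed), minimise
# the total weighted distance; used on small well-separated lists.
oracleMatch <- function(reference, other, gate = 0.15) {
  nR <- nrow(reference)
  dist <- outer(seq_len(nR), seq_len(nrow(other)), function(i, j)
    sqrt((reference$deltaH[i] - other$deltaH[j])^2 +
           ((reference$deltaN[i] - other$deltaN[j]) / 5)^2))
  bestMap <- NULL; bestCost <- Inf
  rec <- function(i, used, map, cost, matched) {
    if (i > nR) {
      # prefer more matches, then lower cost
      if (is.null(bestMap) || matched > attr(bestMap, "matched") ||
          (matched == attr(bestMap, "matched") && cost < bestCost)) {
        attr(map, "matched") <- matched
        bestMap <<- map; bestCost <<- cost
      }
      return(invisible())
    }
    rec(i + 1, used, c(map, NA), cost, matched) # leave unmatched
    for (j in seq_len(ncol(dist)))
      if (!(j %in% used) && dist[i, j] <= gate)
        rec(i + 1, c(used, j), c(map, j), cost + dist[i, j], matched + 1)
  }
  rec(1, integer(), integer(), 0, 0)
  bestMap
}

# Small helper: a noiseless titration design used by several tests.
noiselessDesign <- function(kd = 31, ratios = c(0, 0.25, 0.5, 1, 2, 5),
                            seed = 1L, noiseSd = 0, ...) {
  titrationDesign(trueKd = kd, ligandRatios = ratios, noiseSd = noiseSd,
                  seed = seed, ...)
}
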