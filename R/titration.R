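# Chemical shift perturbation analysis of fast-exchange titrations:
# CSP computation, peak matching with exchange-broadening detection,
# interface calling by the mean + 2 SD rule, and dissociation-constant
# fitting with the quadratic 1:1 bound-fraction model.

#' Chemical shift perturbation between a free and a bound peak
#'
#' \deqn{CSP = \sqrt{(\delta^H_{free}-\delta^H_{bound})^2 +
#'   ((\delta^N_{free}-\delta^N_{bound})/5)^2}}
#'
#' The 1/5 weight scales the 15N axis onto the 1H ppm scale. The value is
#' symmetric in the two peaks and invariant under sign flips of either shift
#' difference.
#'
#' @param free,bound single-row data frames (or lists) with fields
#'   \code{residue}, \code{deltaH}, \code{deltaN}
#' @param nitrogenWeight down-scaling factor for the nitrogen axis
#' @return CSP in ppm (non-negative scalar)
#' @export
computeCsp <- function(free, bound, nitrogenWeight = 5) {
  if (free$residue != bound$residue)
    stop("peak pairing error: residues ", free$residue, " and ",
         bound$residue, " do not match", call. = FALSE)
  weightedShiftDistance(free$deltaH - bound$deltaH,
                        free$deltaN - bound$deltaN, nitrogenWeight)
}

#' Match peaks of a titration point against the assigned reference
#'
#' Assignments are usually known only for the free spectrum; later points
#' are matched by proximity. Each reference peak is paired with the nearest
#' peak of the other list in weighted shift distance
#' \eqn{\sqrt{\Delta H^2 + (\Delta N/5)^2}} provided it falls within
#' \code{gate}; distance ties are broken towards the candidate with the
#' lower residue id (with a warning). Reference residues with no candidate
#' inside the gate are reported as broadened: their peaks have exchanged out.
#'
#' @param reference peak data frame carrying trusted residue ids
#' @param other peak data frame for a later titration point
#' @param gate maximal weighted distance (ppm) for an acceptable match
#' @return list with \code{matches} (data frame: residue, otherIndex,
#'   distance) and \code{broadened} (integer residue ids)
#' @export
matchPeaks <- function(reference, other, gate = 0.15) {
  m <- lapply(seq_len(nrow(reference)), function(i) {
    d <- weightedShiftDistance(reference$deltaH[i] - other$deltaH,
                               reference$deltaN[i] - other$deltaN)
    ok <- which(d <= gate)
    if (!length(ok)) return(NULL)
    best <- ok[d[ok] == min(d[ok])]
    if (length(best) > 1) {
      warning("distance tie while matching reference residue ",
              reference$residue[i], "; choosing lower candidate residue id")
      best <- best[order(other$residue[best])]
    }
    c(residue = reference$residue[i], otherIndex = best[1],
      distance = d[best[1]])
  })
  keep <- !vapply(m, is.null, TRUE)
  matches <- as.data.frame(do.call(rbind, m[keep]))
  if (!nrow(matches))
    matches <- data.frame(residue = integer(), otherIndex = integer(),
                          distance = numeric())
  dup <- duplicated(matches$otherIndex) |
    duplicated(matches$otherIndex, fromLast = TRUE)
  if (any(dup)) {
    claims <- split(matches$residue[dup], matches$otherIndex[dup])
    stop("ambiguous peak matching: reference residues ",
         paste(vapply(claims, function(x) paste(x, collapse = "+"), ""),
               collapse = ", "),
         " claim the same target peak", call. = FALSE)
  }
  list(matches = matches,
       broadened = as.integer(reference$residue[!keep]))
}

#' Per-residue CSP profile between an endpoint and the free spectrum
#'
#' Computes one CSP per assigned residue between the chosen endpoint (by
#' default the last, most ligand-saturated point) and the ligand-free
#' reference. Residues whose peaks are absent from the endpoint are flagged
#' \code{broadened} and carry \code{NA} instead of a number: exchange
#' broadening is qualitative interface evidence, not a measurable shift.
#'
#' @param series a \linkS4class{TitrationSeries}; the first point must have
#'   ligand concentration 0
#' @param endpoint index of the titration point to compare against the free
#'   reference
#' @param gate matching gate passed to [matchPeaks()] when the endpoint list
#'   lacks residue ids
#' @return data frame with columns \code{residue}, \code{csp} (ppm, NA when
#'   broadened) and \code{broadened} (logical)
#' @export
cspProfile <- function(series, endpoint = nPoints(series), gate = 0.15) {
  stopIfNot(endpoint >= 1 && endpoint <= nPoints(series),
            "endpoint index out of range")
  stopIfNot(ligandTotal(series)[1] == 0,
            "first titration point must be the ligand-free reference")
  ref <- peakList(series, 1)
  end <- peakList(series, endpoint)

  if (!is.null(end$residue) && !anyDuplicated(end$residue)) {
    idx <- match(ref$residue, end$residue)
  } else {
    mm <- matchPeaks(ref, end, gate)
    idx <- rep(NA_integer_, nrow(ref))
    idx[match(mm$matches$residue, ref$residue)] <- mm$matches$otherIndex
  }
  csp <- weightedShiftDistance(ref$deltaH - end$deltaH[idx],
                               ref$deltaN - end$deltaN[idx])
  data.frame(residue = ref$residue, csp = csp, broadened = is.na(idx))
}

#' Call the binding interface by the mean + 2 SD rule
#'
#' The cutoff is the mean CSP plus \code{sdMultiplier} standard deviations,
#' both computed over non-broadened residues only; broadened residues are
#' omitted from the statistics and reported separately. A residue belongs to
#' the interface if its CSP is strictly above the cutoff.
#'
#' @param records data frame from [cspProfile()]
#' @param sdMultiplier cutoff multiplier (default 2)
#' @param sdType "population" (divide by n, default) or "sample" (n - 1)
#' @return an \linkS4class{InterfaceCall}
#' @export
callInterface <- function(records, sdMultiplier = 2,
                          sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  ok <- !records$broadened & !is.na(records$csp)
  if (sum(ok) < 3)
    stop("degenerate input: need >= 3 non-broadened CSPs", call. = FALSE)
  x <- records$csp[ok]
  mu <- mean(x)
  s <- if (sdType == "population") sqrt(mean((x - mu)^2)) else stats::sd(x)
  thr <- mu + sdMultiplier * s
  new("InterfaceCall",
      threshold = thr, mean = mu, sd = s,
      interfaceResidues = sort(as.integer(records$residue[ok &
                                                          records$csp > thr])),
      excludedBroadened = sort(as.integer(records$residue[records$broadened])))
}

#' Fraction of protein bound under the 1:1 equilibrium
#'
#' Closed-form root of the binding equilibrium with mass balance:
#' \deqn{f_b = \frac{([P]_t+[L]_t+K_d) -
#'   \sqrt{([P]_t+[L]_t+K_d)^2 - 4[P]_t[L]_t}}{2[P]_t}}
#'
#' @param pt,lt total protein and ligand concentrations (same units as kd)
#' @param kd dissociation constant
#' @return bound fraction in [0, 1]; vectorised over all arguments
#' @export
boundFraction <- function(pt, lt, kd) {
  if (any(pt <= 0)) stop("pt must be > 0", call. = FALSE)
  if (any(lt < 0) || any(kd < 0)) stop("lt and kd must be >= 0", call. = FALSE)
  s <- pt + lt + kd
  disc <- pmax(s^2 - 4 * pt * lt, 0) # guard tiny negative round-off
  # conjugate form of (s - sqrt(disc)) / (2 pt): algebraically identical,
  # but avoids catastrophic cancellation when kd >> pt, lt
  2 * lt / (s + sqrt(disc))
}

#' Predicted CSP under the quadratic 1:1 binding model
#'
#' \deqn{CSP_{obs} = CSP_{max} \, f_b([P]_t, [L]_t, K_d)}
#' with \eqn{f_b} from [boundFraction()] — in fast exchange the observed peak
#' position is the population-weighted average of the free and bound
#' positions, so the perturbation scales with the bound fraction.
#'
#' @inheritParams boundFraction
#' @param cspMax maximal CSP (ppm) at saturation
#' @return predicted CSP in ppm, within \code{[0, cspMax]}
#' @export
predictCsp <- function(pt, lt, kd, cspMax) {
  cspMax * boundFraction(pt, lt, kd)
}

# CSP observations for a residue set against the free reference, one row per
# residue, one column per non-zero titration point; broadened observations NA.
cspObservations <- function(series, residues) {
  ref <- peakList(series, 1)
  idxRef <- match(residues, ref$residue)
  stopIfNot(!anyNA(idxRef), "some requested residues are unassigned at ratio 0")
  nz <- which(ligandTotal(series) > 0)
  obs <- sapply(nz, function(i) {
    p <- peakList(series, i)
    j <- match(residues, p$residue)
    weightedShiftDistance(ref$deltaH[idxRef] - p$deltaH[j],
                          ref$deltaN[idxRef] - p$deltaN[j])
  })
  obs <- matrix(obs, nrow = length(residues),
                dimnames = list(residues, NULL))
  list(obs = obs, pt = proteinTotal(series)[nz], lt = ligandTotal(series)[nz])
}

# Profiled least squares: for a fixed Kd the model is linear in the
# per-residue CSP_max, so CSP_max is solved in closed form and the search is
# one-dimensional in log(Kd).
profiledSse <- function(logKd, obs, pt, lt) {
  fb <- boundFraction(pt, lt, exp(logKd))
  denom <- sum(fb^2)
  amp <- pmax(as.vector(obs %*% fb) / denom, 0)
  resid <- obs - outer(amp, fb)
  list(sse = sum(resid^2), cspMax = amp, residuals = as.vector(resid))
}

fitKdCore <- function(obs, pt, lt, kdRange = c(1e-4, 1e6)) {
  f <- function(lk) profiledSse(lk, obs, pt, lt)$sse
  opt <- stats::optimize(f, log(kdRange), tol = 1e-10)
  kd <- exp(opt$minimum)
  c(list(kd = kd), profiledSse(opt$minimum, obs, pt, lt))
}

# Basic (reversed-percentile) bootstrap interval on the log scale.
# With only a handful of titration points the bootstrap distribution of
# Kd is strongly skewed, and the plain percentile interval under-covers
# (its upper bound tracks the skewed point estimate); the basic interval
# reflects the quantiles about the estimate and is the standard remedy.
# Working in log(Kd) keeps both bounds positive.
basicBootCi <- function(kdHat, kdBoot, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(log(kdBoot), c(1 - a, a), names = FALSE)
  exp(2 * log(kdHat) - q)
}

#' Fit the dissociation constant to a titration series
#'
#' Nonlinear least squares of [predictCsp()] against the observed CSPs of
#' the selected residues at every non-zero titration point. In "shared"
#' mode a single Kd is estimated jointly with one \eqn{CSP_{max}} per
#' residue; in "per-residue" mode each residue gets its own (Kd,
#' \eqn{CSP_{max}}) pair. Because the model is linear in \eqn{CSP_{max}}
#' for fixed Kd, the amplitudes are profiled out and the search is
#' one-dimensional in log(Kd), which is fast and has no convergence
#' failures. Uncertainties come from a seeded nonparametric bootstrap over
#' titration points; the 95\% interval is the basic (reversed-percentile)
#' bootstrap interval computed on the log scale, which stays calibrated
#' under the skew that few-point resampling produces and keeps both
#' bounds positive.
#'
#' @param series a \linkS4class{TitrationSeries}
#' @param residues residue ids to fit; they must be present (non-broadened)
#'   at every non-zero point. If NULL, all residues present everywhere whose
#'   endpoint CSP exceeds half the [callInterface()] threshold are used.
#' @param mode "shared" (one global Kd) or "per-residue"
#' @param nBoot bootstrap resamples (default 500)
#' @param seed seed for the bootstrap resampling
#' @return a \linkS4class{BindingFit}
#' @export
fitKd <- function(series, residues = NULL,
                  mode = c("shared", "per-residue"),
                  nBoot = 500, seed = 1L) {
  mode <- match.arg(mode)
  nz <- which(ligandTotal(series) > 0)
  if (length(nz) < 2)
    stop("underdetermined: need >= 2 non-zero titration points", call. = FALSE)

  if (is.null(residues)) {
    prof <- cspProfile(series)
    call <- callInterface(prof)
    ok <- !prof$broadened & prof$csp > call@threshold / 2
    residues <- prof$residue[ok]
    if (!length(residues))
      stop("no residues pass the minimum-CSP filter", call. = FALSE)
  }
  dat <- cspObservations(series, residues)
  if (anyNA(dat$obs))
    stop("selected residues must be non-broadened at all used points",
         call. = FALSE)

  bootOne <- function(obs, pt, lt, fitFun) {
    est <- fitFun(obs, pt, lt)
    boots <- withSeed(seed, {
      replicate(nBoot, {
        k <- sample(length(pt), replace = TRUE)
        b <- fitFun(obs[, k, drop = FALSE], pt[k], lt[k])
        c(b$kd, b$cspMax)
      })
    })
    list(est = est, boots = boots)
  }

  if (mode == "shared") {
    r <- bootOne(dat$obs, dat$pt, dat$lt, fitKdCore)
    kdBoot <- r$boots[1, ]
    new("BindingFit",
        kd = r$est$kd,
        kdStderr = stats::sd(kdBoot),
        kdCI = matrix(basicBootCi(r$est$kd, kdBoot),
                      1, 2, dimnames = list(NULL, c("lower", "upper"))),
        cspMax = stats::setNames(r$est$cspMax, rownames(dat$obs)),
        cspMaxStderr = apply(r$boots[-1, , drop = FALSE], 1, stats::sd),
        residuals = r$est$residuals,
        fitMode = "shared", nBoot = as.integer(nBoot))
  } else {
    res <- lapply(seq_len(nrow(dat$obs)), function(i) {
      bootOne(dat$obs[i, , drop = FALSE], dat$pt, dat$lt, fitKdCore)
    })
    kd <- vapply(res, function(r) r$est$kd, 0)
    names(kd) <- rownames(dat$obs)
    ci <- t(vapply(res, function(r)
      basicBootCi(r$est$kd, r$boots[1, ]),
      numeric(2)))
    colnames(ci) <- c("lower", "upper")
    new("BindingFit",
        kd = kd,
        kdStderr = vapply(res, function(r) stats::sd(r$boots[1, ]), 0),
        kdCI = ci,
        cspMax = stats::setNames(vapply(res, function(r) r$est$cspMax, 0),
                                 rownames(dat$obs)),
        cspMaxStderr = vapply(res, function(r) stats::sd(r$boots[2, ]), 0),
        residuals = unlist(lapply(res, function(r) r$est$residuals)),
        fitMode = "per-residue", nBoot = as.integer(nBoot))
  }
}
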