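# 15N relaxation: per-residue mono-exponential T1/T2 fitting, steady-state
# heteronuclear NOE ratios, and rule-based flexibility flags.

#' Fit a mono-exponential decay to one residue's intensities
#'
#' Least squares of \eqn{I(t) = I_0 e^{-t/T}} in intensity space (a log
#' transform would be undefined at the near-zero and negative intensities
#' that noisy long delays produce). Starting values are deterministic:
#' \eqn{I_0} = the first intensity, \eqn{T} = the delay whose intensity is
#' nearest \eqn{I_0/e}. Standard errors come from the parameter covariance
#' of the fit.
#'
#' @param delays relaxation delays in seconds (>= 3 values)
#' @param intensities peak intensities at those delays
#' @return list with \code{T}, \code{I0}, \code{stderrT}, \code{stderrI0},
#'   \code{residualNorm}, \code{ok} (FALSE when the data do not decay and
#'   the fit is flagged rather than returned)
#' @export
fitDecay <- function(delays, intensities) {
  delays <- unname(as.numeric(delays))
  intensities <- unname(as.numeric(intensities))
  stopIfNot(length(delays) == length(intensities),
            "delays and intensities must have equal length")
  stopIfNot(length(delays) >= 3, "need >= 3 points for a decay fit")
  if (length(unique(intensities)) == 1)
    stop("degenerate input: all intensities equal", call. = FALSE)

  i0 <- intensities[1]
  tGuess <- delays[which.min(abs(intensities - i0 / exp(1)))]
  if (tGuess <= 0) tGuess <- max(delays) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-t / T),
                      data = list(y = intensities, t = delays),
                      start = list(I0 = i0, T = tGuess),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(T = NA_real_, I0 = NA_real_, stderrT = NA_real_,
                stderrI0 = NA_real_, residualNorm = NA_real_, ok = FALSE))
  co <- stats::coef(fit)
  # divergent = no measurable decay on this grid (T far beyond the
  # longest delay, i.e. the best "decay" is a flat or growing line)
  if (!is.finite(co[["T"]]) || co[["T"]] <= 0 ||
      co[["T"]] > 100 * max(delays))
    return(list(T = NA_real_, I0 = NA_real_, stderrT = NA_real_,
                stderrI0 = NA_real_, residualNorm = NA_real_, ok = FALSE))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, T = NA_real_))
  list(T = unname(co[["T"]]), I0 = unname(co[["I0"]]),
       stderrT = unname(se[["T"]]), stderrI0 = unname(se[["I0"]]),
       residualNorm = sqrt(sum(stats::resid(fit)^2)), ok = TRUE)
}

#' Fit T1 or T2 decays for every residue of a relaxation series
#'
#' Residues whose decays cannot be fit (non-decaying or divergent) are kept
#' in the output with \code{ok = FALSE} and NA values; the rest of the table
#' is unaffected.
#'
#' @param series a \linkS4class{RelaxationSeries} of kind "T1" or "T2"
#' @return data frame with columns \code{residue}, \code{value} (s),
#'   \code{stderr}, \code{I0}, \code{residualNorm}, \code{ok}
#' @export
fitRelaxation <- function(series) {
  stopIfNot(series@kind %in% c("T1", "T2"),
            "fitRelaxation needs a T1 or T2 series")
  m <- intensities(series)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    f <- tryCatch(fitDecay(delays(series), m[i, ]),
                  error = function(e) list(T = NA_real_, I0 = NA_real_,
                                           stderrT = NA_real_,
                                           stderrI0 = NA_real_,
                                           residualNorm = NA_real_,
                                           ok = FALSE))
    data.frame(residue = as.integer(rownames(m)[i]), value = f$T,
               stderr = f$stderrT, I0 = f$I0,
               residualNorm = f$residualNorm, ok = f$ok)
  })
  do.call(rbind, rows)
}

#' Steady-state heteronuclear NOE ratio
#'
#' Ratio of cross-peak intensity in the proton-saturated spectrum to the
#' unsaturated one. The standard error uses first-order propagation of a
#' common spectral noise level \eqn{\sigma}:
#' \deqn{\sigma_{NOE} = |ratio| \sqrt{(\sigma/I_{sat})^2 +
#'   (\sigma/I_{unsat})^2}}
#'
#' @param saturated,unsaturated cross-peak intensities (vectorised)
#' @param noise spectral noise level in intensity units
#' @return data frame with columns \code{ratio} and \code{stderr}
#' @export
hetNoe <- function(saturated, unsaturated, noise = 0) {
  if (any(unsaturated == 0))
    stop("unsaturated intensity must be non-zero", call. = FALSE)
  ratio <- saturated / unsaturated
  data.frame(ratio = ratio,
             stderr = abs(ratio) * sqrt((noise / saturated)^2 +
                                        (noise / unsaturated)^2))
}

#' hetNOE ratios for a relaxation series
#'
#' @param series a \linkS4class{RelaxationSeries} of kind "hetNOE"
#' @return data frame with columns \code{residue}, \code{value},
#'   \code{stderr}
#' @export
hetNoeProfile <- function(series) {
  stopIfNot(series@kind == "hetNOE", "hetNoeProfile needs a hetNOE series")
  m <- intensities(series)
  r <- hetNoe(m[, "sat"], m[, "unsat"], series@noiseEstimate)
  data.frame(residue = as.integer(rownames(m)), value = r$ratio,
             stderr = r$stderr)
}

#' Flag backbone flexibility from relaxation observables
#'
#' Residues with hetNOE below \code{cutoff} are flagged flexible; values at
#' or below zero are labelled "highly flexible" (large-amplitude ps-ns
#' motion, typical of disordered tails). Lower T1 and higher T2 accompany
#' such motion and are reported alongside when available, but the flag is
#' driven by the hetNOE, the most direct ps-ns probe. Residues missing a
#' hetNOE value are skipped with a message.
#'
#' @param noe data frame (residue, value) from [hetNoeProfile()]
#' @param t1,t2 optional data frames from [fitRelaxation()]
#' @param cutoff hetNOE below which a residue is called flexible
#' @return data frame with columns \code{residue}, \code{hetNoe}, \code{t1},
#'   \code{t2}, \code{flexibility} ("rigid", "flexible", "highly flexible")
#' @export
flexibilityProfile <- function(noe, t1 = NULL, t2 = NULL, cutoff = 0.5) {
  bad <- is.na(noe$value)
  if (any(bad))
    message("skipping ", sum(bad), " residue(s) without hetNOE values")
  noe <- noe[!bad, ]
  cls <- ifelse(noe$value <= 0, "highly flexible",
                ifelse(noe$value < cutoff, "flexible", "rigid"))
  out <- data.frame(residue = noe$residue, hetNoe = noe$value,
                    t1 = NA_real_, t2 = NA_real_, flexibility = cls)
  if (!is.null(t1)) out$t1 <- t1$value[match(out$residue, t1$residue)]
  if (!is.null(t2)) out$t2 <- t2$value[match(out$residue, t2$residue)]
  out
}
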