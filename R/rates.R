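#' Kinetic rate constants from omics measurements
#'
#' First-order degradation rates follow directly from half-lives,
#' \eqn{k = \ln 2 / t_{1/2}}; basal transcription and translation rates are
#' chosen so that the deterministic gene-expression module has its fixed point
#' exactly at the measured mRNA count and protein concentration:
#' \deqn{k_{TC,basal} = \frac{k_{TCd}\, m^*\,(k_{G,in}+k_{G,ac})}{k_{G,ac}\, GCN}, \qquad
#'       k_{TL} = \frac{p^*\, k_{TLd}}{m^*_{nM}}.}
#' With the gene on/off process at equilibrium (active copies
#' \eqn{GCN\,k_{G,ac}/(k_{G,ac}+k_{G,in})}), steady-state mRNA equals
#' \eqn{m^*} molecules per cell and steady-state protein equals \eqn{p^*} nM.
#'
#' All half-lives are supplied in hours; returned rates are per second.
#'
#' @param half_life half-life in hours, > 0.
#' @return rate constant in 1/s.
#' @examples
#' mrnaDegradationRate(9) * 3600   # ln(2)/9 per hour
#' @export
mrnaDegradationRate <- function(half_life) {
  if (any(!is.finite(half_life) | half_life <= 0))
    stop("mRNA half-life must be positive and finite")
  log(2) / (half_life * 3600)
}

#' @rdname mrnaDegradationRate
#' @export
proteinDegradationRate <- function(half_life) {
  if (any(!is.finite(half_life) | half_life <= 0))
    stop("protein half-life must be positive and finite")
  log(2) / (half_life * 3600)
}

#' @rdname mrnaDegradationRate
#' @param kTCd mRNA degradation rate (1/s).
#' @param mRNA_count steady-state mRNA molecules per cell.
#' @param kG_in,kG_ac gene inactivation/activation rates (1/s), kG_ac > 0.
#' @param GCN gene copy number, > 0.
#' @export
basalTranscriptionRate <- function(kTCd, mRNA_count, kG_in, kG_ac, GCN) {
  if (any(kG_ac <= 0)) stop("kG_ac must be positive")
  if (any(GCN <= 0)) stop("gene copy number must be positive")
  (kTCd * mRNA_count) * (kG_in + kG_ac) / (kG_ac * GCN)
}

#' @rdname mrnaDegradationRate
#' @param protein_conc steady-state protein concentration (nM).
#' @param kTLd protein degradation rate (1/s).
#' @param mRNA_conc mRNA concentration (nM), > 0 unless protein_conc is 0.
#' @export
translationRate <- function(protein_conc, kTLd, mRNA_conc) {
  if (any(protein_conc < 0)) stop("protein concentration must be >= 0")
  out <- numeric(length(protein_conc))
  nz <- protein_conc > 0
  if (any(nz & (!is.finite(mRNA_conc) | mRNA_conc <= 0)))
    stop("mRNA concentration must be positive where protein is produced")
  out[nz] <- protein_conc[nz] * kTLd[if (length(kTLd) > 1) nz else 1] /
    mRNA_conc[if (length(mRNA_conc) > 1) nz else 1]
  out
}

#' Convert molecules per cell to nanomolar and back
#'
#' \eqn{nM = mpc \times 10^9 / (N_A V)} with \eqn{N_A} Avogadro's number and
#' \eqn{V} the compartment volume in liters. The two functions compose to the
#' identity.
#'
#' @param count molecules per cell.
#' @param conc concentration in nM.
#' @param volume compartment volume in liters, > 0.
#' @return concentration in nM (\code{mpcToNM}) or molecules per cell
#'   (\code{nMToMpc}).
#' @examples
#' mpcToNM(602214, 1e-12)   # ~1 nM in a 1 pL cell
#' @export
mpcToNM <- function(count, volume) {
  if (any(!is.finite(volume) | volume <= 0))
    stop("compartment volume must be positive")
  count * 1e9 / (.AVOGADRO * volume)
}

#' @rdname mpcToNM
#' @export
nMToMpc <- function(conc, volume) {
  if (any(!is.finite(volume) | volume <= 0))
    stop("compartment volume must be positive")
  conc * .AVOGADRO * volume / 1e9
}

#' Hill activation fraction
#'
#' \eqn{h(x; K, n) = (x/K)^n / (1 + (x/K)^n)}, the fractional occupancy used
#' in transcriptional activator/repressor terms. Monotone increasing in x,
#' equal to 1/2 at \eqn{x = K} for any Hill coefficient.
#'
#' @param x regulator concentration (nM), >= 0.
#' @param K half-maximal concentration (nM), > 0.
#' @param n Hill coefficient, >= 1.
#' @return fraction in [0, 1).
#' @examples
#' hillActivation(2, 1, 4)  # 16/17
#' @export
hillActivation <- function(x, K, n) {
  if (any(!is.finite(K) | K <= 0)) stop("K must be positive")
  if (any(n < 1)) stop("Hill coefficient must be >= 1")
  r <- (x / K)^n
  r / (1 + r)
}

#' Default half-maximal concentration for a new regulatory interaction
#'
#' The half-maximal constant is initialized to half the regulator protein's
#' initial concentration. A regulator starting at zero (e.g. an activated
#' transcription factor absent before stimulation) falls back to half the
#' model-wide median of nonzero protein initial concentrations, so that K_A
#' stays positive; the fallback is reported via a message.
#'
#' @param regulator_conc regulator initial concentration (nM), >= 0.
#' @param fallback positive fallback concentration (nM) used when
#'   \code{regulator_conc} is 0 (already halved by the caller's convention:
#'   the fallback passed here is a concentration, the function halves it).
#' @return K_A in nM, > 0.
#' @export
initialKA <- function(regulator_conc, fallback = 1) {
  if (any(regulator_conc < 0)) stop("regulator concentration must be >= 0")
  out <- regulator_conc / 2
  zero <- out == 0
  if (any(zero)) {
    if (fallback <= 0) stop("fallback concentration must be positive")
    message(sprintf("initialKA: %d regulator(s) at 0 nM, using fallback %g/2 nM",
                    sum(zero), fallback))
    out[zero] <- fallback / 2
  }
  out
}

#' Logarithmic calibration grid
#'
#' A grid of candidate parameter values spanning \code{decades} orders of
#' magnitude in total, centered on the default in log10 space:
#' \code{default * 10^seq(-decades/2, decades/2, length.out = points)}.
#' With one-sided spans the grid covers \code{decades} orders below or above
#' the default.
#'
#' @param default positive center value.
#' @param decades total log10 span (default 3).
#' @param points number of grid values (default 15), >= 2.
#' @param span "centered" (default), "one_sided_down" or "one_sided_up".
#' @return strictly increasing numeric vector of length \code{points}.
#' @examples
#' logGrid(1)   # 0.0316 ... 31.6
#' @export
logGrid <- function(default, decades = 3, points = 15, span = c("centered",
                    "one_sided_down", "one_sided_up")) {
  span <- match.arg(span)
  if (default <= 0) stop("grid default must be positive")
  if (points < 2) stop("grid needs at least 2 points")
  if (decades <= 0) stop("grid span must be positive")
  expo <- switch(span,
                 centered = seq(-decades / 2, decades / 2, length.out = points),
                 one_sided_down = seq(-decades, 0, length.out = points),
                 one_sided_up = seq(0, decades, length.out = points))
  default * 10^expo
}
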