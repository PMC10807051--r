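#' Transcription flux of one gene under Hill regulation
#'
#' Flux in molecules per second:
#' \deqn{v = g_{active} \cdot k_{TC,basal} \cdot
#'   \left(1 + \sum_{A} h(A; K_A, n_A)\right)
#'   \prod_{R} \left(1 - h(R; K_R, n_R)\right)}
#' with \eqn{h} the Hill fraction ([hillActivation()]). Without regulators the
#' flux is purely basal; an activator at its half-maximal concentration
#' multiplies it by 1.5; a saturated repressor silences it.
#'
#' @param gene gene symbol present in the model.
#' @param model a \linkS4class{MechModel}.
#' @param state named numeric vector of species concentrations (nM), must
#'   cover all regulators of the gene and be non-negative.
#' @param activeCopies number of active gene copies; defaults to the on/off
#'   equilibrium \code{GCN * kG_ac / (kG_ac + kG_in)}.
#' @return flux in molecules/s.
#' @export
transcriptionFlux <- function(gene, model, state, activeCopies = NULL) {
  i <- match(gene, model@genes$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  g <- model@genes[i, ]
  tars <- model@tars[model@tars$target_gene == gene, , drop = FALSE]
  regs <- tars$regulator
  if (length(regs) && (anyNA(state[regs]) || any(state[regs] < 0)))
    stop("state must provide non-negative concentrations for regulators: ",
         paste(regs, collapse = ", "))
  if (is.null(activeCopies))
    activeCopies <- g$copy_number * g$kG_ac / (g$kG_ac + g$kG_in)
  activeCopies * g$kTC_basal * .tarMultiplier(tars, state)
}

## Precompile the model into the pieces the ODE right-hand side needs.
.compileModel <- function(model) {
  sp <- model@species; gn <- model@genes; rl <- model@ratelaws
  spNames <- sp$species
  nSp <- length(spNames)
  stateNames <- c(spNames, if (nrow(gn)) paste0("g_", gn$gene))
  ## stoichiometry matrix and flux expressions for the mass-action rate laws
  S <- matrix(0, nrow = nSp, ncol = nrow(rl),
              dimnames = list(spNames, rl$ratelaw))
  exprs <- vector("list", nrow(rl))
  parms <- numeric(0)
  for (j in seq_len(nrow(rl))) {
    re <- .parseSpeciesList(rl$reactants[j])
    pr <- .parseSpeciesList(rl$products[j])
    if (length(re)) S[names(re), j] <- S[names(re), j] - re
    if (length(pr)) S[names(pr), j] <- S[names(pr), j] + pr
    exprs[[j]] <- str2lang(rl$formula[j])
    p <- .parseParams(rl$parameters[j])
    clash <- intersect(names(p), names(parms))
    bad <- clash[abs(parms[clash] - p[clash]) > 0]
    if (length(bad))
      stop("conflicting values for shared ratelaw parameter(s): ",
           paste(bad, collapse = ", "))
    parms <- c(parms, p[setdiff(names(p), names(parms))])
  }
  ## per-gene vectors and TAR groupings
  volByComp <- setNames(model@compartments$volume,
                        model@compartments$compartment)
  geneInfo <- NULL
  if (nrow(gn)) {
    mIdx <- match(gn$mRNA_species, spNames)
    conv <- 1e9 / (.AVOGADRO * volByComp[sp$compartment[mIdx]])
    tarsByGene <- lapply(gn$gene, function(g) {
      tg <- model@tars[model@tars$target_gene == g, , drop = FALSE]
      if (nrow(tg) == 0) return(NULL)
      list(regIdx = match(tg$regulator, spNames),
           act = tg$sign == "activator", K = tg$K_A, n = tg$n_A)
    })
    geneInfo <- list(mIdx = mIdx, conv = unname(conv),
                     kGac = gn$kG_ac, kGin = gn$kG_in, GCN = gn$copy_number,
                     kTCb = gn$kTC_basal, kTCd = gn$kTCd,
                     tars = tarsByGene)
  }
  env <- new.env(parent = baseenv())
  for (nm in names(parms)) assign(nm, parms[[nm]], envir = env)
  list(stateNames = stateNames, nSp = nSp, S = S, exprs = exprs, env = env,
       genes = geneInfo)
}

#' Assemble the ODE right-hand side of a model
#'
#' Builds the derivative function integrating: gene on/off switching
#' (\code{dg/dt = kG_ac (GCN - g) - kG_in g}), Hill-regulated transcription
#' and first-order mRNA degradation for every gene record, and all tabulated
#' rate laws (translation, protein degradation, signaling stubs) evaluated as
#' written. Species concentrations are in nM; active gene copies are counts.
#' Transcription flux in molecules/s is converted to nM/s through the
#' compartment volume of the gene's mRNA species.
#'
#' @param model a valid \linkS4class{MechModel}.
#' @return list with \code{func(t, y, parms)} in \pkg{deSolve} form,
#'   \code{y0} (named initial state: species initial concentrations and
#'   equilibrium active copies) and \code{stateNames}.
#' @seealso [simulateModel()]
#' @export
buildRHS <- function(model) {
  stopifnot(is(model, "MechModel"))
  validObject(model)
  cm <- .compileModel(model)
  nSp <- cm$nSp
  gi <- cm$genes
  nGenes <- if (is.null(gi)) 0L else length(gi$mIdx)
  nRl <- length(cm$exprs)
  env <- cm$env
  func <- function(t, y, parms) {
    ycl <- pmax(y, 0)
    dy <- numeric(length(y))
    if (nRl) {
      sv <- ycl[seq_len(nSp)]
      for (i in seq_len(nSp)) assign(cm$stateNames[i], sv[i], envir = env)
      flux <- vapply(cm$exprs, eval, numeric(1), envir = env)
      dy[seq_len(nSp)] <- as.numeric(cm$S %*% flux)
    }
    if (nGenes) {
      g <- ycl[nSp + seq_len(nGenes)]
      dy[nSp + seq_len(nGenes)] <- gi$kGac * (gi$GCN - g) - gi$kGin * g
      for (k in seq_len(nGenes)) {
        mult <- 1
        tg <- gi$tars[[k]]
        if (!is.null(tg)) {
          h <- hillActivation(ycl[tg$regIdx], tg$K, tg$n)
          mult <- (1 + sum(h[tg$act])) * prod(1 - h[!tg$act])
        }
        mi <- gi$mIdx[k]
        dy[mi] <- dy[mi] + gi$conv[k] * g[k] * gi$kTCb[k] * mult -
          gi$kTCd[k] * ycl[mi]
      }
    }
    list(dy)
  }
  y0 <- model@species$initial_nM
  if (nGenes)
    y0 <- c(y0, gi$GCN * gi$kGac / (gi$kGac + gi$kGin))
  names(y0) <- cm$stateNames
  list(func = func, y0 = y0, stateNames = cm$stateNames)
}

#' Dose specification
#'
#' A step change of a ligand species concentration at an onset time.
#'
#' @param species ligand species name.
#' @param concentration concentration set at onset (nM), >= 0.
#' @param onset onset time in seconds (default 0, i.e. at simulation start).
#' @return data.frame row usable in the \code{doses} argument of
#'   [simulateModel()].
#' @export
doseSpec <- function(species, concentration, onset = 0) {
  stopifnot(concentration >= 0, onset >= 0)
  data.frame(species = species, concentration = concentration, onset = onset,
             stringsAsFactors = FALSE)
}

#' Simulate a model deterministically
#'
#' Integrates the full ODE system with a stiff solver (\pkg{deSolve} lsoda,
#' rtol 1e-8, atol 1e-10 by default). Doses are applied as concentration
#' steps: onset-0 doses modify the initial state, later onsets are solver
#' events. An optional pre-equilibration phase integrates the undosed system
#' first and starts the reported trajectory from its endpoint, so that
#' stimulations begin from a settled no-ligand state. Output is reported,
#' not integrated, with tiny solver negatives clipped to zero.
#'
#' @param model a valid \linkS4class{MechModel}.
#' @param hours duration of the reported simulation in hours.
#' @param doses data.frame from [doseSpec()] rows (rbind for several), or NULL.
#' @param nOut number of output time points (default 241).
#' @param preEquilibrateHours length of the undosed settling phase (default 0).
#' @param rtol,atol solver tolerances.
#' @param times optional explicit output times in seconds (overrides
#'   \code{hours}/\code{nOut}).
#' @return a \linkS4class{TimeCourse}.
#' @export
simulateModel <- function(model, hours = 48, doses = NULL, nOut = 241,
                          preEquilibrateHours = 0, rtol = 1e-8, atol = 1e-10,
                          times = NULL) {
  stopifnot(is(model, "MechModel"))
  rhs <- buildRHS(model)
  y0 <- rhs$y0
  if (preEquilibrateHours > 0) {
    pre <- deSolve::ode(y = y0, times = c(0, preEquilibrateHours * 3600),
                        func = rhs$func, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(pre, "istate")[1] < 0)
      stop("pre-equilibration solver failure")
    y0 <- pmax(pre[nrow(pre), -1], 0)
    names(y0) <- rhs$stateNames
  }
  if (is.null(times)) times <- seq(0, hours * 3600, length.out = nOut)
  events <- NULL
  if (!is.null(doses) && nrow(doses)) {
    bad <- setdiff(doses$species, rhs$stateNames)
    if (length(bad)) stop("dose species not in model: ",
                          paste(bad, collapse = ", "))
    atStart <- doses$onset <= times[1]
    y0[doses$species[atStart]] <- doses$concentration[atStart]
    if (any(!atStart)) {
      events <- list(data = data.frame(var = doses$species[!atStart],
                                       time = doses$onset[!atStart],
                                       value = doses$concentration[!atStart],
                                       method = "rep"))
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs$func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("solver failure; last successful time %.6g s",
                 sol[nrow(sol), 1]))
  vals <- pmax(unclass(sol)[, -1, drop = FALSE], 0)
  colnames(vals) <- rhs$stateNames
  new("TimeCourse", times = as.numeric(sol[, 1]), values = vals,
      provenance = list(doses = doses, rtol = rtol, atol = atol,
                        preEquilibrateHours = preEquilibrateHours,
                        solver = "lsoda"))
}

#' Check trajectories for steady state
#'
#' A species is at steady state over the simulated window when its relative
#' drift \code{|end - start| / max(start, eps)} does not exceed
#' \code{relTol}; the boundary is inclusive.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param species character vector of state names (default: all species).
#' @param relTol relative drift tolerance (default 0.01).
#' @param eps floor for the denominator (default 1e-9 nM).
#' @return named logical vector.
#' @export
steadyStateCheck <- function(tc, species = NULL, relTol = 0.01, eps = 1e-9) {
  stopifnot(is(tc, "TimeCourse"))
  if (is.null(species)) species <- colnames(tc@values)
  bad <- setdiff(species, colnames(tc@values))
  if (length(bad)) stop("species not in time course: ",
                        paste(bad, collapse = ", "))
  v0 <- tc@values[1, species]
  v1 <- tc@values[nrow(tc@values), species]
  drift <- abs(v1 - v0) / pmax(v0, eps)
  ## inclusive boundary, robust to floating-point representation of the drift
  setNames(drift <= relTol * (1 + 1e-9), species)
}

## Relative drift helper shared with the basal-rate fit.
.relDrift <- function(tc, species, eps = 1e-9) {
  v0 <- tc@values[1, species]
  v1 <- tc@values[nrow(tc@values), species]
  abs(v1 - v0) / pmax(v0, eps)
}
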