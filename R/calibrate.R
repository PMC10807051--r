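## Integrate the model under each condition: one shared no-ligand
## pre-equilibration, then one dosed run per condition. Returns a named list
## of TimeCourse objects.
.simulateConditions <- function(model, conditions, hours = 48,
                                preEquilibrateHours = 0, nOut = 97,
                                rtol = 1e-8, atol = 1e-10) {
  rhs <- buildRHS(model)
  y0 <- rhs$y0
  if (preEquilibrateHours > 0) {
    pre <- deSolve::ode(y = y0, times = c(0, preEquilibrateHours * 3600),
                        func = rhs$func, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(pre, "istate")[1] < 0) stop("pre-equilibration solver failure")
    y0 <- pmax(pre[nrow(pre), -1], 0)
    names(y0) <- rhs$stateNames
  }
  times <- seq(0, hours * 3600, length.out = nOut)
  out <- vector("list", length(conditions))
  names(out) <- names(conditions)
  for (cn in names(conditions)) {
    y <- y0
    doses <- conditions[[cn]]
    if (!is.null(doses) && nrow(doses)) {
      bad <- setdiff(doses$species, rhs$stateNames)
      if (length(bad)) stop("dose species not in model: ",
                            paste(bad, collapse = ", "))
      y[doses$species] <- doses$concentration
    }
    sol <- deSolve::ode(y = y, times = times, func = rhs$func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure under condition %s", cn))
    vals <- pmax(unclass(sol)[, -1, drop = FALSE], 0)
    colnames(vals) <- rhs$stateNames
    out[[cn]] <- new("TimeCourse", times = as.numeric(sol[, 1]), values = vals,
                     provenance = list(doses = doses, condition = cn,
                                       preEquilibrateHours = preEquilibrateHours))
  }
  out
}

#' Sum of squared errors between simulation and fold-change data
#'
#' Compares simulated fold-change trajectories (value at t divided by value
#' at the first reported time) with observed fold-change data, summing
#' squared differences over all observables, time points and conditions.
#' Simulated values are linearly interpolated to the data times; every data
#' time must lie within the simulated range.
#'
#' @param sims named list of \linkS4class{TimeCourse} objects, one per
#'   condition (names matching \code{data$condition}).
#' @param data data.frame with columns condition, species (state name; or
#'   observable plus a \code{mapping}), time_h and value (fold change
#'   relative to time zero).
#' @param mapping optional named character vector translating
#'   \code{data$observable} to state names.
#' @param eps denominator floor for the simulated baseline (default 1e-9 nM).
#' @return scalar SSE, >= 0; additive over conditions.
#' @export
timeCourseSSE <- function(sims, data, mapping = NULL, eps = 1e-9) {
  if (!"species" %in% names(data)) {
    if (is.null(mapping) || !"observable" %in% names(data))
      stop("data needs a 'species' column or an 'observable' column plus a mapping")
    data$species <- unname(mapping[data$observable])
    if (anyNA(data$species))
      stop("mapping missing for observable(s): ",
           paste(unique(data$observable[is.na(data$species)]), collapse = ", "))
  }
  missCond <- setdiff(unique(data$condition), names(sims))
  if (length(missCond))
    stop("no simulation for condition(s): ", paste(missCond, collapse = ", "))
  sse <- 0
  for (cn in unique(data$condition)) {
    d <- data[data$condition == cn, , drop = FALSE]
    tc <- sims[[cn]]
    tsec <- d$time_h * 3600
    if (any(tsec < tc@times[1] - 1e-6) ||
        any(tsec > tc@times[length(tc@times)] + 1e-6))
      stop("data time outside simulated range for condition ", cn)
    for (sp in unique(d$species)) {
      if (!sp %in% colnames(tc@values))
        stop("data species not in simulation: ", sp)
      di <- d[d$species == sp, , drop = FALSE]
      base <- max(tc@values[1, sp], eps)
      fc <- stats::approx(tc@times, tc@values[, sp], xout = di$time_h * 3600,
                          rule = 2)$y / base
      sse <- sse + sum((fc - di$value)^2)
    }
  }
  sse
}

## Pick the best grid index. Values whose objective is within a small
## absolute/relative band of the minimum count as ties (guards against
## solver-level noise steering a flat profile); ties resolve to the value
## log-closest to the default, then the smaller.
.tieBreak <- function(grid, obj, default, tolAbs = 1e-9, tolRel = 1e-6) {
  best <- min(obj)
  band <- if (is.finite(best)) max(tolAbs, tolRel * abs(best)) else 0
  cand <- which(obj <= best + band)
  if (length(cand) > 1) {
    dist <- abs(log10(grid[cand] / default))
    cand <- cand[dist == min(dist)]
    if (length(cand) > 1) cand <- cand[which.min(grid[cand])]
  }
  cand[1]
}

#' Fit basal transcription rates to restore no-ligand steady state
#'
#' Sequential coordinate fit of the basal transcription rate constants of the
#' expansion-added genes, one at a time in the order the genes were added.
#' A gene whose mRNA already drifts less than \code{driftTol} over the
#' no-ligand window is skipped. Otherwise the rate is varied over a
#' log-spaced grid ([logGrid()]; the incumbent value is the grid center) and
#' the value minimizing the relative drift of that gene's mRNA is fixed
#' before the next gene is explored. If no grid value reaches the tolerance
#' the argmin is kept with a warning.
#'
#' @param model an expanded \linkS4class{MechModel}.
#' @param order character vector of genes to fit (default: expansion-added
#'   genes in table order).
#' @param hours no-ligand assessment window (default 48).
#' @param driftTol relative drift tolerance (default 0.01).
#' @param gridPoints,gridDecades,span grid specification ([logGrid()]).
#' @param rtol,atol solver tolerances.
#' @return list with \code{model} (updated) and \code{fits}
#'   (\linkS4class{FitResults}).
#' @export
fitBasalRates <- function(model, order = NULL, hours = 48, driftTol = 0.01,
                          gridPoints = 15, gridDecades = 3,
                          span = "centered", rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(model, "MechModel"))
  if (is.null(order))
    order <- model@genes$gene[model@genes$origin == "expansion"]
  bad <- setdiff(order, model@genes$gene)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  rows <- list(); profiles <- list()
  for (oi in seq_along(order)) {
    g <- order[oi]
    gi <- match(g, model@genes$gene)
    mSp <- model@genes$mRNA_species[gi]
    default <- model@genes$kTC_basal[gi]
    tc <- simulateModel(model, hours = hours, nOut = 9, rtol = rtol,
                        atol = atol)
    drift0 <- .relDrift(tc, mSp)
    if (drift0 <= driftTol) {
      rows[[g]] <- data.frame(parameter = sprintf("kTC_basal[%s]", g),
                              default = default, chosen = default,
                              objective = drift0, objectiveAtDefault = drift0,
                              orderIndex = oi, skipped = TRUE)
      next
    }
    grid <- logGrid(default, decades = gridDecades, points = gridPoints,
                    span = span)
    obj <- vapply(grid, function(v) {
      m2 <- model
      m2@genes$kTC_basal[gi] <- v
      tryCatch(.relDrift(simulateModel(m2, hours = hours, nOut = 9,
                                       rtol = rtol, atol = atol), mSp),
               error = function(e) Inf)
    }, numeric(1))
    pick <- .tieBreak(grid, obj, default)
    if (obj[pick] > driftTol)
      warning(sprintf("kTC_basal[%s]: no grid value reaches drift tolerance (best %.3g), keeping argmin",
                      g, obj[pick]))
    model@genes$kTC_basal[gi] <- grid[pick]
    model@provenance <- c(model@provenance,
                          sprintf("fitted kTC_basal[%s]: %.6g -> %.6g", g,
                                  default, grid[pick]))
    rows[[g]] <- data.frame(parameter = sprintf("kTC_basal[%s]", g),
                            default = default, chosen = grid[pick],
                            objective = obj[pick],
                            objectiveAtDefault = drift0,
                            orderIndex = oi, skipped = FALSE)
    profiles[[sprintf("kTC_basal[%s]", g)]] <-
      data.frame(value = grid, objective = obj)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), default = numeric(0),
               chosen = numeric(0), objective = numeric(0),
               objectiveAtDefault = numeric(0), orderIndex = integer(0),
               skipped = logical(0))
  rownames(tab) <- NULL
  list(model = model, fits = new("FitResults", table = tab,
                                 profiles = profiles))
}

#' Fit half-maximal regulator concentrations by sequential grid search
#'
#' Coordinate-descent calibration of the half-maximal constants (K_A) of the
#' expansion-added regulatory interactions against fold-change time-course
#' data under a set of stimulation conditions. Parameters are fitted one at
#' a time in the order the interactions were added: each K_A is varied over a
#' log-spaced grid centered on its current value, the model is
#' pre-equilibrated without ligand and simulated under every condition, and
#' the grid value minimizing the summed SSE ([timeCourseSSE()]) is frozen
#' before moving on. Because the incumbent value sits on the grid, the total
#' SSE never increases along the fit sequence. A simulation failure at a grid
#' value scores +Inf and is logged. Ties prefer the value log-closest to the
#' default, then the smaller.
#'
#' @param model an expanded \linkS4class{MechModel} with basal rates settled.
#' @param data fold-change data, see [timeCourseSSE()].
#' @param conditions named list of dose data.frames ([doseSpec()]), names
#'   matching \code{data$condition}.
#' @param order integer or character selection of TAR rows to fit (default:
#'   expansion-added TARs in table order). Character entries use the
#'   "regulator->target" syntax.
#' @param hours stimulation window (default 48).
#' @param preEquilibrateHours no-ligand settling before dosing (default 100).
#' @param gridPoints,gridDecades,span grid specification ([logGrid()]).
#' @param refine logical; golden-section refinement between the best grid
#'   value's neighbors (default FALSE, pure grid output).
#' @param sweeps number of passes over the parameter sequence (default 1,
#'   the single sequential pass; more sweeps iterate the coordinate descent
#'   with each grid re-centered on the incumbent value).
#' @param mapping optional observable-to-species mapping for \code{data}.
#' @param nOut output resolution of the fitting simulations.
#' @param rtol,atol solver tolerances.
#' @return list with \code{model} (updated K_A values) and \code{fits}
#'   (\linkS4class{FitResults} with full SSE profiles).
#' @export
fitKA <- function(model, data, conditions, order = NULL, hours = 48,
                  preEquilibrateHours = 100, gridPoints = 15,
                  gridDecades = 3, span = "centered", refine = FALSE,
                  mapping = NULL, nOut = 49, rtol = 1e-8, atol = 1e-10,
                  sweeps = 1) {
  stopifnot(is(model, "MechModel"))
  tarId <- paste0(model@tars$regulator, "->", model@tars$target_gene)
  if (is.null(order)) {
    idx <- which(model@tars$origin == "expansion")
  } else if (is.character(order)) {
    idx <- match(order, tarId)
    if (anyNA(idx)) stop("unknown TAR(s): ",
                         paste(order[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(order)
  objective <- function(m) {
    sims <- .simulateConditions(m, conditions, hours = hours,
                                preEquilibrateHours = preEquilibrateHours,
                                nOut = nOut, rtol = rtol, atol = atol)
    timeCourseSSE(sims, data, mapping = mapping)
  }
  rows <- list(); profiles <- list()
  for (sw in seq_len(sweeps)) {
  for (oi in seq_along(idx)) {
    i <- idx[oi]
    id <- tarId[i]
    default <- model@tars$K_A[i]
    grid <- logGrid(default, decades = gridDecades, points = gridPoints,
                    span = span)
    obj <- vapply(grid, function(v) {
      m2 <- model
      m2@tars$K_A[i] <- v
      tryCatch(objective(m2), error = function(e) {
        warning(sprintf("K_A[%s] = %.4g: simulation failed (%s), scored +Inf",
                        id, v, conditionMessage(e)))
        Inf
      })
    }, numeric(1))
    pick <- .tieBreak(grid, obj, default)
    chosen <- grid[pick]; best <- obj[pick]
    if (refine && is.finite(best) && pick > 1 && pick < length(grid)) {
      opt <- stats::optimize(function(v) {
        m2 <- model; m2@tars$K_A[i] <- v
        tryCatch(objective(m2), error = function(e) Inf)
      }, lower = grid[pick - 1], upper = grid[pick + 1])
      if (opt$objective < best) {
        chosen <- opt$minimum; best <- opt$objective
      }
    }
    model@tars$K_A[i] <- chosen
    model@provenance <- c(model@provenance,
                          sprintf("fitted K_A[%s]: %.6g -> %.6g (SSE %.6g)",
                                  id, default, chosen, best))
    rows[[id]] <- data.frame(parameter = sprintf("K_A[%s]", id),
                             default = default, chosen = chosen,
                             objective = best,
                             objectiveAtDefault = obj[(gridPoints + 1) %/% 2 +
                                                        (gridPoints %% 2 == 0)],
                             orderIndex = oi,
                             skipped = FALSE)
    profiles[[sprintf("K_A[%s]", id)]] <- data.frame(value = grid,
                                                     objective = obj)
  }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), default = numeric(0),
               chosen = numeric(0), objective = numeric(0),
               objectiveAtDefault = numeric(0), orderIndex = integer(0),
               skipped = logical(0))
  rownames(tab) <- NULL
  list(model = model, fits = new("FitResults", table = tab,
                                 profiles = profiles))
}
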