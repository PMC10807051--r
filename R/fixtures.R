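#' Specification for the synthetic toy system
#'
#' Bundles the knobs of the synthetic model/network/omics generators: a small
#' base model with a ligand-to-transcription-factor stub (a ligand species
#' converts the overlap gene's protein into an active transcription factor,
#' which decays back and whose ligand is slowly cleared), a random signed
#' association network over new genes plus the overlap gene, and log-uniform
#' omics tables. All randomness flows from the single seed; repeated
#' generation is identical.
#'
#' @param nBaseGenes number of base-model genes (>= 1; the first is the
#'   overlap gene STAT1).
#' @param nNewGenes,nEdges size of the generated association network.
#' @param fracNegative fraction of repressive (negative) edges.
#' @param seed integer seed fixing all randomness.
#' @param volume compartment volume in liters (default 1e-12, the order of a
#'   mammalian cell).
#' @param ligActivation,ligWeakActivation TF activation rate constants for
#'   the strong (IFNG) and weak (EGF) ligand, 1/(nM s).
#' @param tfDeactivation active-TF decay rate (1/s).
#' @param ligClearance first-order ligand clearance (1/s).
#' @return a list of class "toySpec".
#' @export
toySpec <- function(nBaseGenes = 3, nNewGenes = 8, nEdges = 14,
                    fracNegative = 0.25, seed = 1, volume = 1e-12,
                    ligActivation = 1e-4, ligWeakActivation = 1e-6,
                    tfDeactivation = 5e-5, ligClearance = 1e-5) {
  stopifnot(nBaseGenes >= 1, nNewGenes >= 1,
            nEdges <= nNewGenes * (nNewGenes + 1) / 2,
            fracNegative >= 0, fracNegative <= 1, volume > 0)
  structure(list(nBaseGenes = nBaseGenes, nNewGenes = nNewGenes,
                 nEdges = nEdges, fracNegative = fracNegative, seed = seed,
                 volume = volume, ligActivation = ligActivation,
                 ligWeakActivation = ligWeakActivation,
                 tfDeactivation = tfDeactivation,
                 ligClearance = ligClearance),
            class = "toySpec")
}

#' Generate a consistent toy base model
#'
#' Builds a small mechanistic model standing in for a large signaling model:
#' one compartment, two ligand species (EGF, IFNG), the overlap gene STAT1
#' whose protein is converted by ligand into an active transcription factor
#' species (aSTAT1, the designated transcriptional regulator of STAT1),
#' further base genes, and per-gene translation/degradation reactions with
#' rate constants derived from synthetic omics, so that the no-ligand state
#' is a fixed point by construction. When the base model has at least two
#' genes, one base regulatory interaction (aSTAT1 activating the second
#' gene) is included.
#'
#' @param spec a [toySpec()].
#' @param dir optional directory; when given, the table set is written there.
#' @return a valid \linkS4class{MechModel}.
#' @export
makeToyBaseModel <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "toySpec"))
  genes <- c("STAT1",
             if (spec$nBaseGenes > 1) paste0("BGENE", seq_len(spec$nBaseGenes - 1)))
  om <- makeSyntheticOmics(genes, seed = spec$seed + 1000L)
  ## fixed, biologically sensible overlap-gene levels
  om[om$gene == "STAT1", c("mRNA_mpc", "protein_nM", "mRNA_half_life_h",
                           "protein_half_life_h")] <- list(50, 80, 8, 40)
  m <- new("MechModel",
           compartments = data.frame(compartment = "Cell",
                                     volume = spec$volume,
                                     annotation = "single well-mixed cell"),
           species = data.frame(
             species = c("EGF", "IFNG", "aSTAT1"),
             compartment = "Cell",
             initial_nM = 0,
             kind = c("other", "other", "protein"),
             annotation = c("epidermal growth factor ligand",
                            "interferon-gamma ligand",
                            "ligand-activated transcription factor"),
             stringsAsFactors = FALSE))
  for (g in genes)
    m <- suppressMessages(makeGeneEntities(m, g, om))$model
  m@genes$origin <- "base"
  m@ratelaws$origin <- "base"
  m@genes$regulator_species[m@genes$gene == "STAT1"] <- "aSTAT1"
  stub <- data.frame(
    ratelaw = c("vActTF", "vDeactTF", "vClrIFNG", "vClrEGF"),
    reactants = c("p_STAT1", "aSTAT1", "IFNG", "EGF"),
    products = c("aSTAT1", "p_STAT1", "", ""),
    formula = c("(k_actIFNG * IFNG + k_actEGF * EGF) * p_STAT1",
                "k_deactTF * aSTAT1",
                "k_clrIFNG * IFNG",
                "k_clrEGF * EGF"),
    parameters = c(sprintf("k_actIFNG=%g;k_actEGF=%g", spec$ligActivation,
                           spec$ligWeakActivation),
                   sprintf("k_deactTF=%g", spec$tfDeactivation),
                   sprintf("k_clrIFNG=%g", spec$ligClearance),
                   sprintf("k_clrEGF=%g", spec$ligClearance)),
    origin = "base", stringsAsFactors = FALSE)
  m@ratelaws <- .bindRows(m@ratelaws, stub)
  if (length(genes) > 1) {
    m@tars <- .bindRows(m@tars, data.frame(
      regulator = "aSTAT1", target_gene = genes[2], sign = "activator",
      K_A = 5, n_A = 4, origin = "base", stringsAsFactors = FALSE))
  }
  m@provenance <- sprintf("toy base model: %d genes, seed %d",
                          length(genes), spec$seed)
  validObject(m)
  if (!is.null(dir)) writeModelTables(m, dir)
  m
}

#' Generate a random signed association network
#'
#' Draws \code{nEdges} unique unordered gene pairs over the new genes
#' (NGENE1..n) plus the overlap gene STAT1. The first edges form a spanning
#' attachment (each new gene links to STAT1 or an earlier new gene) so every
#' gene is connected to the overlap component; remaining edges are uniform
#' random pairs. Coefficient magnitudes are uniform in [0.05, 0.6] with the
#' stated fraction negative. Deterministic given the spec seed.
#'
#' @param spec a [toySpec()].
#' @param path optional TSV output path (header gene1/gene2/coefficient).
#' @return an \linkS4class{AssociationNetwork}.
#' @export
makeToyNetwork <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toySpec"))
  newGenes <- paste0("NGENE", seq_len(spec$nNewGenes))
  allGenes <- c("STAT1", newGenes)
  .withLocalSeed(spec$seed + 2000L, {
    g1 <- character(0); g2 <- character(0)
    seen <- character(0)
    for (i in seq_len(min(spec$nNewGenes, spec$nEdges))) {
      anchor <- sample(c("STAT1", newGenes[seq_len(i - 1)]), 1)
      g1 <- c(g1, anchor); g2 <- c(g2, newGenes[i])
      seen <- c(seen, .pairKey(anchor, newGenes[i]))
    }
    while (length(g1) < spec$nEdges) {
      pair <- sample(allGenes, 2)
      key <- .pairKey(pair[1], pair[2])
      if (key %in% seen) next
      g1 <- c(g1, pair[1]); g2 <- c(g2, pair[2]); seen <- c(seen, key)
    }
    coef <- stats::runif(length(g1), 0.05, 0.6) *
      ifelse(stats::runif(length(g1)) < spec$fracNegative, -1, 1)
    net <- new("AssociationNetwork",
               edges = data.frame(gene1 = g1, gene2 = g2, coefficient = coef,
                                  stringsAsFactors = FALSE))
    if (!is.null(path)) {
      utils::write.table(
        data.frame(gene1 = g1, gene2 = g2,
                   coefficient = format(coef, digits = 17, trim = TRUE)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    net
  })
}

#' Generate synthetic per-gene omics tables
#'
#' Log-uniform draws emulating absolute transcriptomic/proteomic
#' measurements: mRNA 1-1000 molecules per cell, protein 0.01-1000 nM, mRNA
#' half-life 1-24 h, protein half-life 10-100 h, gene copy number 2.
#' Genes listed in \code{phosphoGenes} additionally receive a phosphoprotein
#' level (a quarter of the protein level). Deterministic given the seed.
#'
#' @param genes character vector of gene symbols.
#' @param seed integer seed.
#' @param phosphoGenes subset of \code{genes} with phosphoprotein data.
#' @return data.frame in the OmicsData layout.
#' @export
makeSyntheticOmics <- function(genes, seed = 1, phosphoGenes = character(0)) {
  genes <- .normSymbol(genes)
  .withLocalSeed(seed, {
    lu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
    n <- length(genes)
    out <- data.frame(
      gene = genes,
      mRNA_mpc = lu(n, 1, 1000),
      protein_nM = lu(n, 0.01, 1000),
      mRNA_half_life_h = lu(n, 1, 24),
      protein_half_life_h = lu(n, 10, 100),
      copy_number = 2,
      phospho_nM = NA_real_,
      stringsAsFactors = FALSE)
    ph <- genes %in% .normSymbol(phosphoGenes)
    out$phospho_nM[ph] <- out$protein_nM[ph] / 4
    out
  })
}

#' Standard two-condition stimulation scenario
#'
#' The growth-factor and growth-factor-plus-interferon dosing used for
#' calibration: EGF 1.5625 nM alone, and EGF 1.5625 nM with IFNG 1.1834 nM,
#' both applied as steps at time zero.
#'
#' @param egf,ifng dose concentrations in nM.
#' @return named list of dose data.frames for [fitKA()] and
#'   [makeGroundTruthTimeCourses()].
#' @export
stimulationConditions <- function(egf = 1.5625, ifng = 1.1834) {
  list("EGF" = doseSpec("EGF", egf),
       "EGF+IFNG" = rbind(doseSpec("EGF", egf), doseSpec("IFNG", ifng)))
}

#' Simulate ground-truth calibration data from a model
#'
#' Sets the given "true" half-maximal constants, pre-equilibrates without
#' ligand, simulates every condition, samples fold-change trajectories on a
#' dense-early/sparse-late grid (default 0, 1, 4, 8, 24, 48 h) and applies
#' multiplicative lognormal noise of the stated coefficient of variation.
#' With \code{noiseCV = 0} the data lie exactly on the model trajectory, so
#' refitting recovers the true constants.
#'
#' @param model an expanded \linkS4class{MechModel}.
#' @param trueKA named numeric vector of half-maximal constants to install,
#'   names in "regulator->target" syntax (NULL keeps current values).
#' @param conditions named list of dose data.frames
#'   ([stimulationConditions()]).
#' @param observables state names to report (default: mRNA species of all
#'   expansion-added genes).
#' @param times_h sampling times in hours.
#' @param noiseCV multiplicative lognormal noise CV (default 0).
#' @param seed noise seed.
#' @param preEquilibrateHours,nOut,rtol,atol simulation settings (match the
#'   fitting defaults so noise-free data sit on the fitted trajectories).
#' @return list with \code{data} (data.frame condition/species/time_h/value)
#'   and \code{model} (with true constants installed).
#' @export
makeGroundTruthTimeCourses <- function(model, trueKA = NULL, conditions,
                                       observables = NULL,
                                       times_h = c(0, 1, 4, 8, 24, 48),
                                       noiseCV = 0, seed = 1,
                                       preEquilibrateHours = 100, nOut = 49,
                                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(model, "MechModel"))
  if (!is.null(trueKA)) {
    tarId <- paste0(model@tars$regulator, "->", model@tars$target_gene)
    idx <- match(names(trueKA), tarId)
    if (anyNA(idx))
      stop("unknown TAR(s): ", paste(names(trueKA)[is.na(idx)], collapse = ", "))
    model@tars$K_A[idx] <- unname(trueKA)
  }
  if (is.null(observables)) {
    isExp <- model@genes$origin == "expansion"
    observables <- model@genes$mRNA_species[isExp]
  }
  sims <- .simulateConditions(model, conditions,
                              hours = max(times_h),
                              preEquilibrateHours = preEquilibrateHours,
                              nOut = nOut, rtol = rtol, atol = atol)
  rows <- list()
  for (cn in names(sims)) {
    tc <- sims[[cn]]
    for (sp in observables) {
      base <- max(tc@values[1, sp], 1e-9)
      fc <- stats::approx(tc@times, tc@values[, sp],
                          xout = times_h * 3600, rule = 2)$y / base
      rows[[paste(cn, sp)]] <- data.frame(condition = cn, species = sp,
                                          time_h = times_h, value = fc,
                                          stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  if (noiseCV > 0) {
    sdlog <- sqrt(log(1 + noiseCV^2))
    data$value <- .withLocalSeed(seed,
      data$value * exp(stats::rnorm(nrow(data), 0, sdlog)))
  }
  list(data = data, model = model)
}
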