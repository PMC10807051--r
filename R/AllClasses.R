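#' @import methods
NULL

## Canonical column layouts for the tab-delimited model tables. The first
## column of each table is the row identifier.
.compartmentCols <- c(compartment = "character", volume = "numeric",
                      annotation = "character")
.speciesCols <- c(species = "character", compartment = "character",
                  initial_nM = "numeric", kind = "character",
                  annotation = "character")
.geneCols <- c(gene = "character", copy_number = "numeric",
               kG_ac = "numeric", kG_in = "numeric",
               kTC_basal = "numeric", kTCd = "numeric",
               mRNA_count = "numeric", mRNA_species = "character",
               protein_species = "character", regulator_species = "character",
               origin = "character")
.ratelawCols <- c(ratelaw = "character", reactants = "character",
                  products = "character", formula = "character",
                  parameters = "character", origin = "character")
.tarCols <- c(regulator = "character", target_gene = "character",
              sign = "character", K_A = "numeric", n_A = "numeric",
              origin = "character")
.omicsCols <- c(gene = "character", mRNA_mpc = "numeric",
                protein_nM = "numeric", mRNA_half_life_h = "numeric",
                protein_half_life_h = "numeric", copy_number = "numeric",
                phospho_nM = "numeric")

.emptyTable <- function(spec) {
  out <- lapply(spec, function(cls) vector(cls, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

.speciesKinds <- c("mRNA", "protein", "phosphoprotein", "other")
.tarSigns <- c("activator", "repressor")

#' Signed gene-gene association network
#'
#' Holds an undirected network of signed gene-gene associations, e.g. the
#' penalized-regression coefficients linking mRNA, protein and chromatin
#' readouts of gene pairs. Each edge carries a nonzero coefficient whose sign
#' decides whether the downstream expansion treats the pair as mutual
#' transcriptional activation (positive) or repression (negative).
#'
#' @slot edges data.frame with columns \code{gene1}, \code{gene2} (uppercase
#'   gene symbols) and \code{coefficient} (finite, nonzero). Unordered gene
#'   pairs are unique; a row with \code{gene1 == gene2} is a self-association.
#'
#' @seealso [loadAssociationEdges()], [filterToSeeds()], [edgesToTARs()]
#' @export
setClass("AssociationNetwork",
         representation(edges = "data.frame"),
         prototype(edges = data.frame(gene1 = character(0),
                                      gene2 = character(0),
                                      coefficient = numeric(0))))

setValidity("AssociationNetwork", function(object) {
  e <- object@edges
  msg <- character(0)
  need <- c("gene1", "gene2", "coefficient")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(!nzchar(e$gene1)) || any(!nzchar(e$gene2)))
      msg <- c(msg, "gene symbols must be non-empty")
    if (any(!is.finite(e$coefficient)) || any(e$coefficient == 0))
      msg <- c(msg, "coefficients must be finite and nonzero")
    key <- .pairKey(e$gene1, e$gene2)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate unordered gene pairs present")
  }
  if (length(msg)) msg else TRUE
})

#' Mechanistic reaction-network model
#'
#' Container for a deterministic mechanistic model defined by tab-delimited
#' tables: compartments, species (concentrations in nM), per-gene expression
#' records (gene copy number, on/off switching rates, basal transcription and
#' mRNA degradation rates), mass-action rate laws, Hill-type transcriptional
#' activator/repressor interactions (TARs), and per-gene omics measurements
#' used for parameterization. All rate constants are in per-second units;
#' half-lives are converted at the reader boundary.
#'
#' Gene on/off state is part of the model's dynamical state but is not a
#' species: only mRNA, protein and (optionally) phosphoprotein of a gene
#' appear in the species table.
#'
#' @slot compartments data.frame: compartment, volume (liters), annotation.
#' @slot species data.frame: species, compartment, initial_nM, kind
#'   (mRNA/protein/phosphoprotein/other), annotation.
#' @slot genes data.frame: gene, copy_number, kG_ac, kG_in (1/s gene
#'   activation/inactivation), kTC_basal (molecules/s per active copy), kTCd
#'   (1/s), mRNA_count (molecules per cell), mRNA_species, protein_species,
#'   regulator_species (species acting as transcriptional regulator when this
#'   gene regulates others; usually the protein), origin ("base"/"expansion").
#' @slot ratelaws data.frame: ratelaw, reactants, products (" + "-separated
#'   species with optional integer stoichiometry prefix), formula (arithmetic
#'   expression over species and parameter names, flux in nM/s), parameters
#'   ("name=value" pairs separated by ";"), origin.
#' @slot tars data.frame: regulator (species), target_gene, sign
#'   (activator/repressor), K_A (nM), n_A (Hill coefficient), origin.
#' @slot omics data.frame: gene, mRNA_mpc, protein_nM, mRNA_half_life_h,
#'   protein_half_life_h, copy_number, phospho_nM (NA if unmeasured).
#' @slot provenance character log of construction/expansion actions.
#'
#' @seealso [readModelTables()], [expandModel()], [simulateModel()]
#' @export
setClass("MechModel",
         representation(compartments = "data.frame",
                        species = "data.frame",
                        genes = "data.frame",
                        ratelaws = "data.frame",
                        tars = "data.frame",
                        omics = "data.frame",
                        provenance = "character"),
         prototype(compartments = .emptyTable(.compartmentCols),
                   species = .emptyTable(.speciesCols),
                   genes = .emptyTable(.geneCols),
                   ratelaws = .emptyTable(.ratelawCols),
                   tars = .emptyTable(.tarCols),
                   omics = .emptyTable(.omicsCols),
                   provenance = character(0)))

.checkCols <- function(df, spec, what) {
  if (!all(names(spec) %in% names(df)))
    sprintf("%s table missing columns: %s", what,
            paste(setdiff(names(spec), names(df)), collapse = ", "))
  else character(0)
}

setValidity("MechModel", function(object) {
  msg <- c(.checkCols(object@compartments, .compartmentCols, "compartments"),
           .checkCols(object@species, .speciesCols, "species"),
           .checkCols(object@genes, .geneCols, "genes"),
           .checkCols(object@ratelaws, .ratelawCols, "ratelaws"),
           .checkCols(object@tars, .tarCols, "tars"),
           .checkCols(object@omics, .omicsCols, "omics"))
  if (length(msg)) return(msg)
  cmp <- object@compartments; sp <- object@species; gn <- object@genes
  rl <- object@ratelaws; tr <- object@tars
  if (nrow(cmp) && any(!is.finite(cmp$volume) | cmp$volume <= 0))
    msg <- c(msg, "compartment volumes must be positive")
  if (anyDuplicated(cmp$compartment))
    msg <- c(msg, "duplicate compartment names")
  if (anyDuplicated(sp$species))
    msg <- c(msg, "duplicate species names")
  if (nrow(sp)) {
    bad <- !(sp$compartment %in% cmp$compartment)
    if (any(bad))
      msg <- c(msg, sprintf("species reference unknown compartment: %s",
                            paste(sp$species[bad], collapse = ", ")))
    if (any(!is.finite(sp$initial_nM) | sp$initial_nM < 0))
      msg <- c(msg, "species initial concentrations must be finite and >= 0")
    if (any(!sp$kind %in% .speciesKinds))
      msg <- c(msg, "species kind must be mRNA/protein/phosphoprotein/other")
  }
  if (anyDuplicated(gn$gene))
    msg <- c(msg, "duplicate gene records")
  if (nrow(gn)) {
    rates <- as.matrix(gn[, c("kG_ac", "kG_in", "kTC_basal", "kTCd")])
    if (any(!is.finite(rates) | rates < 0))
      msg <- c(msg, "gene rate constants must be finite and >= 0")
    if (any(gn$copy_number < 0))
      msg <- c(msg, "gene copy numbers must be >= 0 (0 only for knockouts)")
    if (any(gn$kG_ac + gn$kG_in <= 0))
      msg <- c(msg, "kG_ac + kG_in must be positive")
    refs <- c(gn$mRNA_species, gn$protein_species, gn$regulator_species)
    bad <- setdiff(refs, sp$species)
    if (length(bad))
      msg <- c(msg, sprintf("gene table references unknown species: %s",
                            paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(rl$ratelaw))
    msg <- c(msg, "duplicate ratelaw ids")
  if (nrow(rl)) {
    for (i in seq_len(nrow(rl))) {
      parts <- c(.parseSpeciesList(rl$reactants[i]),
                 .parseSpeciesList(rl$products[i]))
      bad <- setdiff(names(parts), sp$species)
      if (length(bad))
        msg <- c(msg, sprintf("ratelaw %s references unknown species: %s",
                              rl$ratelaw[i], paste(bad, collapse = ", ")))
      pars <- .parseParams(rl$parameters[i])
      if (length(pars) && any(!is.finite(pars) | pars < 0))
        msg <- c(msg, sprintf("ratelaw %s has non-finite or negative parameters",
                              rl$ratelaw[i]))
      syms <- all.vars(str2lang(rl$formula[i]))
      bad <- setdiff(syms, c(sp$species, names(pars)))
      if (length(bad))
        msg <- c(msg, sprintf("ratelaw %s formula has unresolved symbols: %s",
                              rl$ratelaw[i], paste(bad, collapse = ", ")))
    }
  }
  if (nrow(tr)) {
    if (any(!tr$sign %in% .tarSigns))
      msg <- c(msg, "TAR sign must be activator or repressor")
    if (any(!is.finite(tr$K_A) | tr$K_A <= 0))
      msg <- c(msg, "TAR K_A must be positive")
    if (any(!is.finite(tr$n_A) | tr$n_A < 1))
      msg <- c(msg, "TAR n_A must be >= 1")
    if (anyDuplicated(paste(tr$regulator, tr$target_gene)))
      msg <- c(msg, "duplicate (regulator, target_gene) TAR pairs")
    bad <- setdiff(tr$regulator, sp$species)
    if (length(bad))
      msg <- c(msg, sprintf("TAR regulators not in species table: %s",
                            paste(bad, collapse = ", ")))
    bad <- setdiff(tr$target_gene, gn$gene)
    if (length(bad))
      msg <- c(msg, sprintf("TAR targets not in gene table: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Report of one model-expansion transaction
#'
#' @slot genesAdded,speciesAdded,ratelawsAdded,tarsAdded integer deltas;
#'   they equal the post-minus-pre model counts for each entity class.
#' @slot provenance data.frame mapping every added entity (entity, type) to
#'   the network edge or omics row that produced it (source).
#' @slot defaultsUsed data.frame (gene, field, value) of parameters that fell
#'   back to base-model means because the omics table lacked them.
#' @slot dropped data.frame (regulator, target_gene, sign, reason) of TAR
#'   candidates removed as exact duplicates or by self-regulation policy.
#' @export
setClass("ExpansionReport",
         representation(genesAdded = "integer", speciesAdded = "integer",
                        ratelawsAdded = "integer", tarsAdded = "integer",
                        provenance = "data.frame",
                        defaultsUsed = "data.frame",
                        dropped = "data.frame"))

#' Deterministic simulation trajectory
#'
#' @slot times numeric vector of output times in seconds, strictly increasing.
#' @slot values numeric matrix, one row per time, one column per state
#'   variable (species in nM, then per-gene active copy numbers named
#'   \code{g_<gene>}).
#' @slot provenance list with solver settings, doses and model summary.
#' @export
setClass("TimeCourse",
         representation(times = "numeric", values = "matrix",
                        provenance = "list"))

setValidity("TimeCourse", function(object) {
  if (length(object@times) != nrow(object@values))
    return("length(times) must equal nrow(values)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Results of a sequential grid-search calibration
#'
#' @slot table data.frame with one row per fitted parameter: parameter id,
#'   default value, chosen value, minimum objective, objective at the
#'   incumbent default, order index, and whether the parameter was skipped
#'   (already satisfying the steady-state criterion).
#' @slot profiles named list of data.frames (grid value, objective) with the
#'   full grid profile per parameter.
#' @export
setClass("FitResults",
         representation(table = "data.frame", profiles = "list"))

#' Single-gene knockout screen report
#'
#' @slot table data.frame with one row per (gene, readout): maximum relative
#'   deviation from wild type over time, terminal relative deviation, and
#'   classification ("observable"/"negligible") at the stated threshold.
#' @slot threshold numeric classification threshold on max relative deviation.
#' @slot readouts character readout species names.
#' @export
setClass("KnockoutScreen",
         representation(table = "data.frame", threshold = "numeric",
                        readouts = "character"))
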