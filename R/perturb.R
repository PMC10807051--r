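#' In-silico knockout of a gene
#'
#' Returns a copy of the model with the gene's copy number, mRNA count and
#' the initial concentrations of its mRNA, protein and (if present)
#' phosphoprotein species set to zero, and its basal transcription rate
#' zeroed so no production remains. Translation is untouched; it is silenced
#' because the mRNA stays identically zero. Other genes' parameters and the
#' species count are never altered, and the operation is idempotent.
#'
#' @param model a \linkS4class{MechModel}.
#' @param gene gene symbol to knock out.
#' @return the knocked-out \linkS4class{MechModel} copy.
#' @export
knockoutGene <- function(model, gene) {
  stopifnot(is(model, "MechModel"))
  gene <- .normSymbol(gene)
  i <- match(gene, model@genes$gene)
  if (is.na(i))
    stop(sprintf("unknown gene '%s'; available: %s", gene,
                 paste(model@genes$gene, collapse = ", ")))
  g <- model@genes[i, ]
  model@genes$kTC_basal[i] <- 0
  model@genes$mRNA_count[i] <- 0
  model@genes$copy_number[i] <- 0
  zeroSp <- c(g$mRNA_species, g$protein_species, paste0("pp_", gene))
  zeroSp <- intersect(zeroSp, model@species$species)
  model@species$initial_nM[model@species$species %in% zeroSp] <- 0
  model@provenance <- c(model@provenance, sprintf("knockout of %s", gene))
  model
}

#' Compare a knockout trajectory to wild type
#'
#' Per readout species, computes the relative deviation
#' \code{|ko - wt| / max(|wt|, eps)} over the shared time grid, reporting its
#' maximum over time and its terminal value, and classifies the readout as
#' "observable" when the maximum deviation exceeds \code{threshold}.
#'
#' @param tcKO,tcWT \linkS4class{TimeCourse} objects on the same time grid
#'   (same doses and solver settings).
#' @param readouts character readout species names.
#' @param threshold classification threshold (default 0.05).
#' @param eps denominator floor (default 1e-9 nM).
#' @param gene optional gene label carried into the report.
#' @return a \linkS4class{KnockoutScreen} with one row per readout.
#' @export
compareToWildType <- function(tcKO, tcWT, readouts, threshold = 0.05,
                              eps = 1e-9, gene = NA_character_) {
  stopifnot(is(tcKO, "TimeCourse"), is(tcWT, "TimeCourse"))
  if (!isTRUE(all.equal(tcKO@times, tcWT@times)))
    stop("knockout and wild-type trajectories must share the time grid")
  bad <- setdiff(readouts, intersect(colnames(tcKO@values),
                                     colnames(tcWT@values)))
  if (length(bad)) stop("readout(s) not in both trajectories: ",
                        paste(bad, collapse = ", "))
  rows <- lapply(readouts, function(sp) {
    dev <- abs(tcKO@values[, sp] - tcWT@values[, sp]) /
      pmax(abs(tcWT@values[, sp]), eps)
    data.frame(gene = gene, readout = sp, maxDeviation = max(dev),
               terminalDeviation = dev[length(dev)],
               classification = if (max(dev) > threshold) "observable"
                                else "negligible",
               stringsAsFactors = FALSE)
  })
  new("KnockoutScreen", table = do.call(rbind, rows), threshold = threshold,
      readouts = readouts)
}

#' Screen single-gene knockouts against wild type
#'
#' Simulates the wild type once under the given dosing scenario, then each
#' single-gene knockout under identical settings, and ranks genes by their
#' maximum relative deviation on the chosen readouts. The screen is
#' deterministic and order-independent: permuting \code{genes} permutes the
#' per-gene reports identically.
#'
#' @param model a \linkS4class{MechModel}.
#' @param genes character vector of genes to knock out (default: all
#'   expansion-added genes).
#' @param readouts readout species names.
#' @param doses dosing scenario (data.frame of [doseSpec()] rows or NULL).
#' @param hours simulated stimulation window (default 48).
#' @param preEquilibrateHours no-ligand settling before dosing (default 0;
#'   use a basal-growth settling phase to mimic pre-stimulation culture).
#' @param threshold classification threshold (default 0.05).
#' @param nOut,rtol,atol solver settings.
#' @return a \linkS4class{KnockoutScreen}; rows sorted by decreasing
#'   per-gene maximum deviation (ties keep input order).
#' @export
screenKnockouts <- function(model, genes = NULL, readouts, doses = NULL,
                            hours = 48, preEquilibrateHours = 0,
                            threshold = 0.05, nOut = 241, rtol = 1e-8,
                            atol = 1e-10) {
  stopifnot(is(model, "MechModel"))
  if (is.null(genes))
    genes <- model@genes$gene[model@genes$origin == "expansion"]
  tcWT <- simulateModel(model, hours = hours, doses = doses, nOut = nOut,
                        preEquilibrateHours = preEquilibrateHours,
                        rtol = rtol, atol = atol)
  tabs <- lapply(genes, function(g) {
    ko <- knockoutGene(model, g)
    tcKO <- simulateModel(ko, hours = hours, doses = doses, nOut = nOut,
                          preEquilibrateHours = preEquilibrateHours,
                          rtol = rtol, atol = atol)
    screenTable(compareToWildType(tcKO, tcWT, readouts,
                                  threshold = threshold, gene = g))
  })
  tab <- do.call(rbind, tabs)
  if (length(genes)) {
    geneMax <- vapply(split(tab$maxDeviation, tab$gene)[unique(tab$gene)],
                      max, numeric(1))
    ord <- unique(tab$gene)[order(-geneMax[unique(tab$gene)])]
    tab <- tab[order(match(tab$gene, ord)), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(gene = character(0), readout = character(0),
                      maxDeviation = numeric(0),
                      terminalDeviation = numeric(0),
                      classification = character(0))
  }
  new("KnockoutScreen", table = tab, threshold = threshold,
      readouts = readouts)
}
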