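.defaultHillCoefficient <- 4

## Transcriptional multiplier for one gene given its TARs and a named
## concentration lookup: (1 + sum of activator Hill terms) *
## prod(1 - repressor Hill terms). Basal transcription is preserved when all
## activators are absent; saturated repressors silence the gene.
.tarMultiplier <- function(tars, conc) {
  if (is.null(tars) || nrow(tars) == 0) return(1)
  h <- hillActivation(pmax(conc[tars$regulator], 0), tars$K_A, tars$n_A)
  act <- tars$sign == "activator"
  (1 + sum(h[act])) * prod(1 - h[!act])
}

## Mean of nonzero, non-NA values; NA if none.
.nzMean <- function(x) {
  x <- x[!is.na(x) & x != 0]
  if (length(x)) mean(x) else NA_real_
}

#' Add the species, reactions and gene record for one new gene
#'
#' Creates the entities a gene contributes to a model: an mRNA and a protein
#' species (plus a phosphoprotein species when the omics row carries a
#' phosphoprotein level), a translation and a protein degradation rate law,
#' and a gene record holding copy number, on/off switching rates, basal
#' transcription and mRNA degradation rates. Rate constants derive from the
#' omics measurements via [mrnaDegradationRate()], [proteinDegradationRate()],
#' [basalTranscriptionRate()] and [translationRate()]; missing omics fields
#' fall back to the mean of the corresponding values over existing model
#' genes (nonzero entries only) and are reported in \code{defaultsUsed}.
#' Adding a gene already present is a no-op with a message.
#'
#' @param model a \linkS4class{MechModel}.
#' @param gene gene symbol (uppercase).
#' @param omics data.frame in the OmicsData layout from which the gene's row
#'   is taken; missing fields are defaulted.
#' @return list with elements \code{model} (updated), \code{speciesAdded},
#'   \code{ratelawsAdded} (character ids) and \code{defaultsUsed} (data.frame
#'   gene/field/value).
#' @seealso [expandModel()]
#' @export
makeGeneEntities <- function(model, gene, omics) {
  stopifnot(is(model, "MechModel"))
  gene <- .normSymbol(gene)
  noDefaults <- data.frame(gene = character(0), field = character(0),
                           value = numeric(0), stringsAsFactors = FALSE)
  if (gene %in% model@genes$gene) {
    message(sprintf("gene %s already in model, nothing added", gene))
    return(list(model = model, speciesAdded = character(0),
                ratelawsAdded = character(0), defaultsUsed = noDefaults))
  }
  row <- omics[.normSymbol(omics$gene) == gene, , drop = FALSE]
  vals <- list()
  for (f in c("mRNA_mpc", "protein_nM", "mRNA_half_life_h",
              "protein_half_life_h", "copy_number", "phospho_nM")) {
    vals[[f]] <- if (nrow(row)) row[[f]][1] else NA_real_
  }
  defaults <- noDefaults
  for (f in c("mRNA_mpc", "protein_nM", "mRNA_half_life_h",
              "protein_half_life_h", "copy_number")) {
    if (is.na(vals[[f]])) {
      fb <- .nzMean(model@omics[[f]])
      if (is.na(fb))
        stop(sprintf("gene %s: missing omics field '%s' and no existing-model values to default from",
                     gene, f))
      vals[[f]] <- fb
      defaults <- rbind(defaults, data.frame(gene = gene, field = f,
                                             value = fb))
    }
  }
  ## gene on/off rates: mean over existing genes, fixed fallback otherwise
  kG_ac <- .nzMean(model@genes$kG_ac)
  kG_in <- .nzMean(model@genes$kG_in)
  if (is.na(kG_ac)) { kG_ac <- 1e-3; defaults <- rbind(defaults,
    data.frame(gene = gene, field = "kG_ac", value = kG_ac)) }
  if (is.na(kG_in)) { kG_in <- 1e-3; defaults <- rbind(defaults,
    data.frame(gene = gene, field = "kG_in", value = kG_in)) }

  if (nrow(model@compartments) == 0)
    stop("model has no compartments; cannot place new species")
  comp <- if (nrow(model@genes)) {
    sp0 <- model@species
    sp0$compartment[match(model@genes$mRNA_species[1], sp0$species)]
  } else model@compartments$compartment[1]
  vol <- model@compartments$volume[match(comp, model@compartments$compartment)]

  kTCd <- mrnaDegradationRate(vals$mRNA_half_life_h)
  kTLd <- proteinDegradationRate(vals$protein_half_life_h)
  mRNA_nM <- mpcToNM(vals$mRNA_mpc, vol)
  kTL <- translationRate(vals$protein_nM, kTLd, mRNA_nM)
  kTC_basal <- basalTranscriptionRate(kTCd, vals$mRNA_mpc, kG_in, kG_ac,
                                      vals$copy_number)

  mSp <- paste0("m_", gene); pSp <- paste0("p_", gene)
  newSp <- data.frame(species = c(mSp, pSp), compartment = comp,
                      initial_nM = c(mRNA_nM, vals$protein_nM),
                      kind = c("mRNA", "protein"),
                      annotation = sprintf("%s of %s", c("mRNA", "protein"),
                                           gene),
                      stringsAsFactors = FALSE)
  hasPhospho <- !is.na(vals$phospho_nM)
  if (hasPhospho) {
    newSp <- rbind(newSp, data.frame(species = paste0("pp_", gene),
                                     compartment = comp,
                                     initial_nM = vals$phospho_nM,
                                     kind = "phosphoprotein",
                                     annotation = sprintf("phosphoprotein of %s",
                                                          gene)))
  }
  kTLname <- paste0("kTL_", gene); kTLdName <- paste0("kTLd_", gene)
  newRl <- data.frame(
    ratelaw = paste0(c("vTL_", "vPD_"), gene),
    reactants = c("", pSp),
    products = c(pSp, ""),
    formula = c(sprintf("%s * %s", kTLname, mSp),
                sprintf("%s * %s", kTLdName, pSp)),
    parameters = c(sprintf("%s=%s", kTLname, format(kTL, digits = 17)),
                   sprintf("%s=%s", kTLdName, format(kTLd, digits = 17))),
    origin = "expansion", stringsAsFactors = FALSE)
  newGn <- data.frame(gene = gene, copy_number = vals$copy_number,
                      kG_ac = kG_ac, kG_in = kG_in, kTC_basal = kTC_basal,
                      kTCd = kTCd, mRNA_count = vals$mRNA_mpc,
                      mRNA_species = mSp, protein_species = pSp,
                      regulator_species = pSp, origin = "expansion",
                      stringsAsFactors = FALSE)
  model@species <- .bindRows(model@species, newSp)
  model@ratelaws <- .bindRows(model@ratelaws, newRl)
  model@genes <- .bindRows(model@genes, newGn)
  omRow <- data.frame(gene = gene, mRNA_mpc = vals$mRNA_mpc,
                      protein_nM = vals$protein_nM,
                      mRNA_half_life_h = vals$mRNA_half_life_h,
                      protein_half_life_h = vals$protein_half_life_h,
                      copy_number = vals$copy_number,
                      phospho_nM = if (hasPhospho) vals$phospho_nM else NA_real_,
                      stringsAsFactors = FALSE)
  model@omics <- .bindRows(model@omics, omRow)
  model@provenance <- c(model@provenance,
                        sprintf("added gene %s (+%d species, +2 ratelaws)",
                                gene, nrow(newSp)))
  list(model = model, speciesAdded = newSp$species,
       ratelawsAdded = newRl$ratelaw, defaultsUsed = defaults)
}

#' Turn association edges into directed Hill regulatory interactions
#'
#' Each undirected signed edge produces two directed transcriptional
#' activator/repressor (TAR) candidates: the regulator species of gene1 acts
#' on gene2 and the regulator species of gene2 acts on gene1, both with the
#' sign given by [classifyEdge()]. Half-maximal constants start at half the
#' regulator's initial concentration ([initialKA()], falling back to half the
#' model-wide median nonzero protein concentration for regulators starting at
#' zero) and the Hill coefficient defaults to 4. Candidates that duplicate an
#' existing or earlier (regulator, target, sign) triple are collapsed; a
#' self-association edge therefore contributes a single autoregulatory TAR.
#' With \code{selfRegulation = "drop"} autoregulation is removed entirely
#' instead.
#'
#' @param net an \linkS4class{AssociationNetwork}; all endpoints must exist
#'   as genes in \code{model}.
#' @param model a \linkS4class{MechModel}.
#' @param selfRegulation "collapse" (default) or "drop".
#' @param hillCoefficient Hill coefficient for all new interactions.
#' @return list with \code{tars} (data.frame rows to add), \code{dropped}
#'   (data.frame with reasons), \code{fallbackKA} (character regulators that
#'   used the fallback half-maximal constant).
#' @export
edgesToTARs <- function(net, model, selfRegulation = c("collapse", "drop"),
                        hillCoefficient = .defaultHillCoefficient) {
  stopifnot(is(net, "AssociationNetwork"), is(model, "MechModel"))
  selfRegulation <- match.arg(selfRegulation)
  e <- net@edges
  gn <- model@genes
  missing <- setdiff(unique(c(e$gene1, e$gene2)), gn$gene)
  if (length(missing))
    stop("network genes absent from model: ", paste(missing, collapse = ", "))
  sp <- model@species
  protConc <- sp$initial_nM[sp$kind == "protein"]
  fallback <- stats::median(protConc[protConc > 0])
  if (!length(protConc) || is.na(fallback)) fallback <- 1
  empty <- .emptyTable(.tarCols)
  droppedCols <- c(.tarCols[c("regulator", "target_gene", "sign")],
                   reason = "character")
  dropped <- .emptyTable(droppedCols)
  out <- empty
  seen <- paste(model@tars$regulator, model@tars$target_gene)
  seenSigned <- paste(model@tars$regulator, model@tars$target_gene,
                      model@tars$sign)
  fallbackKA <- character(0)
  for (i in seq_len(nrow(e))) {
    sgn <- classifyEdge(e$coefficient[i])
    ends <- c(e$gene1[i], e$gene2[i])
    for (k in 1:2) {
      regGene <- ends[k]; tgt <- ends[3 - k]
      reg <- gn$regulator_species[match(regGene, gn$gene)]
      isSelf <- regGene == tgt
      if (isSelf && selfRegulation == "drop") {
        dropped <- rbind(dropped, data.frame(regulator = reg,
                                             target_gene = tgt, sign = sgn,
                                             reason = "self-regulation"))
        next
      }
      key <- paste(reg, tgt)
      if (key %in% seen) {
        reason <- if (paste(reg, tgt, sgn) %in% seenSigned) "duplicate"
                  else "sign-conflict"
        if (reason == "sign-conflict")
          warning(sprintf("TAR %s -> %s: conflicting sign %s dropped (first occurrence kept)",
                          reg, tgt, sgn))
        dropped <- rbind(dropped, data.frame(regulator = reg,
                                             target_gene = tgt, sign = sgn,
                                             reason = reason))
        next
      }
      conc <- sp$initial_nM[match(reg, sp$species)]
      KA <- if (conc > 0) conc / 2 else {
        fallbackKA <- c(fallbackKA, reg)
        fallback / 2
      }
      out <- rbind(out, data.frame(regulator = reg, target_gene = tgt,
                                   sign = sgn, K_A = KA,
                                   n_A = hillCoefficient,
                                   origin = "expansion",
                                   stringsAsFactors = FALSE))
      seen <- c(seen, key)
      seenSigned <- c(seenSigned, paste(reg, tgt, sgn))
    }
  }
  if (length(fallbackKA))
    message(sprintf("K_A fallback (regulator initially 0 nM) used for: %s",
                    paste(unique(fallbackKA), collapse = ", ")))
  list(tars = out, dropped = dropped, fallbackKA = unique(fallbackKA))
}

#' Expand a mechanistic model with an association network
#'
#' The core expansion transaction: every network gene not yet in the model
#' receives species, reactions and a gene record ([makeGeneEntities()]), then
#' every edge becomes a pair of directed Hill-type transcriptional
#' interactions ([edgesToTARs()]). By default each target gene's basal
#' transcription rate is then rescaled by the reciprocal of its resting
#' regulatory multiplier so that the omics-derived initial state remains an
#' exact fixed point of the expanded model (\code{rebalanceBasal}); this is
#' the analytic counterpart of grid-fitting basal rates to restore steady
#' state. The operation is all-or-nothing and idempotent: re-expanding with
#' the same network adds nothing.
#'
#' @param model a valid \linkS4class{MechModel}.
#' @param net a validated \linkS4class{AssociationNetwork}.
#' @param omics data.frame in the OmicsData layout providing measurements for
#'   the new genes; defaults to the model's own omics table.
#' @param selfRegulation,hillCoefficient passed to [edgesToTARs()].
#' @param rebalanceBasal logical; rescale basal transcription of genes that
#'   gained TARs so the initial state stays steady (default TRUE).
#' @return list with \code{model} (expanded \linkS4class{MechModel}) and
#'   \code{report} (an \linkS4class{ExpansionReport} whose counts equal the
#'   model deltas).
#' @examples
#' \donttest{
#' dir <- tempfile(); netf <- tempfile()
#' spec <- toySpec(nNewGenes = 3, nEdges = 3, seed = 1)
#' m <- makeToyBaseModel(spec, dir)
#' net <- makeToyNetwork(spec, netf)
#' om <- makeSyntheticOmics(nodes(net), seed = 1)
#' ex <- expandModel(m, net, om)
#' ex$report
#' }
#' @export
expandModel <- function(model, net, omics = NULL,
                        selfRegulation = c("collapse", "drop"),
                        hillCoefficient = .defaultHillCoefficient,
                        rebalanceBasal = TRUE) {
  stopifnot(is(model, "MechModel"), is(net, "AssociationNetwork"))
  validObject(model); validObject(net)
  selfRegulation <- match.arg(selfRegulation)
  if (is.null(omics)) omics <- model@omics
  pre <- modelCounts(model)
  m <- model
  newGenes <- setdiff(nodes(net), m@genes$gene)
  prov <- data.frame(entity = character(0), type = character(0),
                     source = character(0), stringsAsFactors = FALSE)
  defaultsUsed <- data.frame(gene = character(0), field = character(0),
                             value = numeric(0), stringsAsFactors = FALSE)
  for (g in newGenes) {
    res <- makeGeneEntities(m, g, omics)
    m <- res$model
    defaultsUsed <- rbind(defaultsUsed, res$defaultsUsed)
    prov <- rbind(prov,
                  data.frame(entity = c(g, res$speciesAdded, res$ratelawsAdded),
                             type = c("gene", rep("species",
                                                  length(res$speciesAdded)),
                                      rep("ratelaw", length(res$ratelawsAdded))),
                             source = sprintf("omics:%s", g)))
  }
  tarRes <- edgesToTARs(net, m, selfRegulation = selfRegulation,
                        hillCoefficient = hillCoefficient)
  if (nrow(tarRes$tars)) {
    m@tars <- .bindRows(m@tars, tarRes$tars)
    prov <- rbind(prov,
                  data.frame(entity = paste(tarRes$tars$regulator, "->",
                                            tarRes$tars$target_gene),
                             type = "tar",
                             source = sprintf("edge:%s", tarRes$tars$target_gene)))
  }
  if (rebalanceBasal && nrow(tarRes$tars)) {
    conc <- setNames(m@species$initial_nM, m@species$species)
    for (g in unique(tarRes$tars$target_gene)) {
      tg <- m@tars[m@tars$target_gene == g, , drop = FALSE]
      mult <- .tarMultiplier(tg, conc)
      i <- match(g, m@genes$gene)
      m@genes$kTC_basal[i] <- m@genes$kTC_basal[i] / mult
      m@provenance <- c(m@provenance,
                        sprintf("rebalanced kTC_basal of %s by 1/%.6g", g, mult))
    }
  }
  m@provenance <- c(m@provenance,
                    sprintf("expansion: +%d genes, +%d TARs (%d candidates dropped)",
                            length(newGenes), nrow(tarRes$tars),
                            nrow(tarRes$dropped)))
  validObject(m)
  post <- modelCounts(m)
  report <- new("ExpansionReport",
                genesAdded = as.integer(post["genes"] - pre["genes"]),
                speciesAdded = as.integer(post["species"] - pre["species"]),
                ratelawsAdded = as.integer(post["ratelaws"] - pre["ratelaws"]),
                tarsAdded = as.integer(post["tars"] - pre["tars"]),
                provenance = prov, defaultsUsed = defaultsUsed,
                dropped = tarRes$dropped)
  list(model = m, report = report)
}

#' Free-parameter inventory of an expanded model
#'
#' Enumerates the parameters the calibration stage treats as unknown: one
#' half-maximal constant per expansion-added regulatory interaction and the
#' mRNA and protein degradation rate constants of every expansion-added gene.
#'
#' @param model an expanded \linkS4class{MechModel}.
#' @return data.frame with columns parameter, type ("K_A", "kTCd", "kTLd"),
#'   gene/target and current value.
#' @export
calibrationInventory <- function(model) {
  stopifnot(is(model, "MechModel"))
  tr <- model@tars[model@tars$origin == "expansion", , drop = FALSE]
  gn <- model@genes[model@genes$origin == "expansion", , drop = FALSE]
  ka <- if (nrow(tr)) data.frame(
    parameter = sprintf("K_A[%s->%s]", tr$regulator, tr$target_gene),
    type = "K_A", gene = tr$target_gene, value = tr$K_A,
    stringsAsFactors = FALSE) else NULL
  deg <- if (nrow(gn)) {
    kTLd <- vapply(gn$gene, function(g) {
      p <- .parseParams(model@ratelaws$parameters[
        match(paste0("vPD_", g), model@ratelaws$ratelaw)])
      unname(p[paste0("kTLd_", g)])
    }, numeric(1))
    rbind(data.frame(parameter = sprintf("kTCd[%s]", gn$gene), type = "kTCd",
                     gene = gn$gene, value = gn$kTCd, stringsAsFactors = FALSE),
          data.frame(parameter = sprintf("kTLd[%s]", gn$gene), type = "kTLd",
                     gene = gn$gene, value = kTLd, stringsAsFactors = FALSE))
  } else NULL
  out <- rbind(ka, deg)
  if (is.null(out)) out <- data.frame(parameter = character(0),
                                      type = character(0),
                                      gene = character(0),
                                      value = numeric(0))
  rownames(out) <- NULL
  out
}
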