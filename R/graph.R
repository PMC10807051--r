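#' Directed influence graph of a model
#'
#' Builds the directed graph of dynamical influence: for every rate law, each
#' species appearing among the reactants or in the kinetic formula influences
#' every reactant and product; for every gene, the gene node influences its
#' mRNA (transcription) and the mRNA its degradation; every regulatory
#' interaction adds an edge from the regulator species to the target gene
#' node. Gene nodes are labelled \code{gene:<symbol>}. Used to predict which
#' species a knockout can possibly affect.
#'
#' @param model a \linkS4class{MechModel}.
#' @return an \pkg{igraph} directed graph whose vertices are species names
#'   and gene nodes.
#' @seealso [knockoutReachable()]
#' @export
regulatoryGraph <- function(model) {
  stopifnot(is(model, "MechModel"))
  sp <- model@species$species
  geneNodes <- paste0("gene:", model@genes$gene)
  from <- character(0); to <- character(0)
  rl <- model@ratelaws
  for (j in seq_len(nrow(rl))) {
    re <- names(.parseSpeciesList(rl$reactants[j]))
    pr <- names(.parseSpeciesList(rl$products[j]))
    infl <- union(re, intersect(all.vars(str2lang(rl$formula[j])), sp))
    aff <- union(re, pr)
    if (length(infl) && length(aff)) {
      from <- c(from, rep(infl, each = length(aff)))
      to <- c(to, rep(aff, times = length(infl)))
    }
  }
  gn <- model@genes
  for (i in seq_len(nrow(gn))) {
    from <- c(from, paste0("gene:", gn$gene[i]))
    to <- c(to, gn$mRNA_species[i])
  }
  tr <- model@tars
  if (nrow(tr)) {
    from <- c(from, tr$regulator)
    to <- c(to, paste0("gene:", tr$target_gene))
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = unique(c(sp, geneNodes, from, to)))
}

#' Species reachable from a gene knockout
#'
#' The set of species whose dynamics can possibly be affected by knocking
#' out a gene, i.e. all vertices reachable in the model's influence graph
#' from the gene node and its mRNA/protein/phosphoprotein species. A readout
#' outside this set cannot deviate from wild type beyond solver noise.
#'
#' @param model a \linkS4class{MechModel}.
#' @param gene gene symbol.
#' @return character vector of reachable species names.
#' @export
knockoutReachable <- function(model, gene) {
  gene <- .normSymbol(gene)
  i <- match(gene, model@genes$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  gr <- regulatoryGraph(model)
  seeds <- intersect(c(paste0("gene:", gene),
                       model@genes$mRNA_species[i],
                       model@genes$protein_species[i],
                       model@genes$regulator_species[i],
                       paste0("pp_", gene)),
                     igraph::V(gr)$name)
  reach <- unique(unlist(lapply(seeds, function(s)
    names(igraph::subcomponent(gr, s, mode = "out")))))
  setdiff(intersect(reach, model@species$species), character(0))
}
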