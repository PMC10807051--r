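#' Read a signed gene-gene association edge list
#'
#' Reads a tab-separated file with three columns (gene1, gene2, coefficient;
#' header optional), validates it and returns an
#' \linkS4class{AssociationNetwork}. Gene symbols are trimmed and matched
#' case-insensitively (stored uppercase); an optional alias map translates
#' alternative symbols (e.g. \code{c("PD-L1" = "CD274", "PD-1" = "PDCD1")}).
#' Rows with zero coefficient are rejected with a warning (the sign rule only
#' defines positive and negative associations). Duplicate unordered gene
#' pairs are collapsed keeping the first occurrence, with a warning.
#'
#' @param path TSV file path.
#' @param aliases optional named character vector, alias -> canonical symbol.
#' @return an \linkS4class{AssociationNetwork}.
#' @seealso [filterToSeeds()], [classifyEdge()]
#' @export
loadAssociationEdges <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("association file not found: ", path)
  if (file.size(path) == 0) return(new("AssociationNetwork"))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 3) {
    if (nrow(raw) == 0)
      return(new("AssociationNetwork"))
    stop("association file must have 3 columns (gene1, gene2, coefficient), found ",
         ncol(raw))
  }
  if (ncol(raw) > 3)
    stop("association file must have 3 columns (gene1, gene2, coefficient), found ",
         ncol(raw))
  rowOffset <- 0L
  first <- raw[1, , drop = TRUE]
  if (is.na(.num(first[[3]]))) {
    ## header row: require the canonical column names
    hdr <- unname(tolower(trimws(unlist(first))))
    if (!identical(hdr, c("gene1", "gene2", "coefficient")))
      stop("association file header must be 'gene1<TAB>gene2<TAB>coefficient', found: ",
           paste(hdr, collapse = ", "))
    raw <- raw[-1, , drop = FALSE]
    rowOffset <- 1L
  }
  if (nrow(raw) == 0) return(new("AssociationNetwork"))
  coef <- .num(raw[[3]])
  if (anyNA(coef))
    stop("non-numeric coefficient at row ",
         paste(which(is.na(coef)) + rowOffset, collapse = ", "))
  g1 <- .normSymbol(raw[[1]], aliases)
  g2 <- .normSymbol(raw[[2]], aliases)
  if (any(!nzchar(g1) | !nzchar(g2)))
    stop("empty gene symbol at row ",
         paste(which(!nzchar(g1) | !nzchar(g2)) + rowOffset, collapse = ", "))
  zero <- coef == 0
  if (any(zero)) {
    warning(sprintf("dropping %d edge(s) with zero coefficient (row %s)",
                    sum(zero), paste(which(zero) + rowOffset, collapse = ", ")))
    g1 <- g1[!zero]; g2 <- g2[!zero]; coef <- coef[!zero]
  }
  key <- .pairKey(g1, g2)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsing %d duplicate unordered pair(s), keeping first: %s",
                    sum(dup), paste(unique(paste(g1[dup], g2[dup], sep = "-")),
                                    collapse = ", ")))
    g1 <- g1[!dup]; g2 <- g2[!dup]; coef <- coef[!dup]
  }
  new("AssociationNetwork",
      edges = data.frame(gene1 = g1, gene2 = g2, coefficient = coef,
                         stringsAsFactors = FALSE))
}

#' Keep only edges touching a set of seed genes
#'
#' Retains exactly the edges with at least one endpoint in \code{seeds}. The
#' operation is idempotent and never grows the network; it may return an
#' empty network.
#'
#' @param net an \linkS4class{AssociationNetwork}.
#' @param seeds non-empty character vector of gene symbols.
#' @param aliases optional alias map applied to the seeds.
#' @return filtered \linkS4class{AssociationNetwork}.
#' @export
filterToSeeds <- function(net, seeds, aliases = NULL) {
  stopifnot(is(net, "AssociationNetwork"))
  if (length(seeds) == 0) stop("seeds must be non-empty")
  seeds <- .normSymbol(seeds, aliases)
  e <- net@edges
  keep <- e$gene1 %in% seeds | e$gene2 %in% seeds
  new("AssociationNetwork", edges = e[keep, , drop = FALSE])
}

#' Regulation sign of an association coefficient
#'
#' Positive coefficients are interpreted as transcriptional activation,
#' negative ones as repression; only the sign matters, not the magnitude.
#' Zero coefficients are rejected (they are already removed at load time).
#'
#' @param coefficient numeric vector of nonzero association coefficients.
#' @return character vector, "activator" or "repressor".
#' @examples
#' classifyEdge(c(0.31, -0.07))
#' @export
classifyEdge <- function(coefficient) {
  if (any(!is.finite(coefficient) | coefficient == 0))
    stop("coefficients must be finite and nonzero")
  ifelse(coefficient > 0, "activator", "repressor")
}
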