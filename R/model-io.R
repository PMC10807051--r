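## Tab-delimited model table dialect:
##   - one file per table: Compartments.txt, Species.txt, Ratelaws.txt,
##     GeneReg.txt, OmicsData.txt, TARs.txt (TARs optional);
##   - header row required, first column is the row identifier;
##   - "nan", "NA" and empty cells are treated as absent;
##   - volumes in liters, concentrations in nM, rates in 1/s, half-lives in
##     hours (converted to rates by the expansion step, stored as given).

.tableFiles <- c(compartments = "Compartments.txt", species = "Species.txt",
                 ratelaws = "Ratelaws.txt", genes = "GeneReg.txt",
                 omics = "OmicsData.txt", tars = "TARs.txt")

.readTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", "nan", ""),
                          check.names = FALSE)
  df
}

.coerceTable <- function(df, spec, what, file) {
  miss <- setdiff(names(spec), names(df))
  if (length(miss))
    stop(sprintf("%s (%s) missing columns: %s", what, file,
                 paste(miss, collapse = ", ")))
  for (nm in names(spec)) {
    if (spec[[nm]] == "numeric") {
      v <- df[[nm]]
      if (!is.numeric(v)) {
        nv <- .num(v)
        bad <- which(!is.na(v) & is.na(nv))
        if (length(bad))
          stop(sprintf("%s (%s): non-numeric value in column %s, row %s",
                       what, file, nm, paste(bad, collapse = ", ")))
        v <- nv
      }
      df[[nm]] <- v
    } else {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "", as.character(df[[nm]]))
    }
  }
  df[, names(spec), drop = FALSE]
}

#' Read a mechanistic model from tab-delimited tables
#'
#' Reads the table set (Compartments, Species, Ratelaws, GeneReg, OmicsData,
#' and optionally TARs) from a directory, validates all cross-references
#' (species/compartment/gene/regulator identity, rate-law formula symbols)
#' and returns a \linkS4class{MechModel}. A missing mandatory table raises a
#' file error; a dangling reference raises an integrity error naming the
#' offending row.
#'
#' @param dir directory containing the tables.
#' @return a validated \linkS4class{MechModel}.
#' @seealso [writeModelTables()], [exportSBML()]
#' @export
readModelTables <- function(dir) {
  if (!dir.exists(dir)) stop("model directory not found: ", dir)
  paths <- file.path(dir, .tableFiles)
  names(paths) <- names(.tableFiles)
  mandatory <- setdiff(names(paths), "tars")
  missing <- mandatory[!file.exists(paths[mandatory])]
  if (length(missing))
    stop("missing model table file(s): ",
         paste(.tableFiles[missing], collapse = ", "))
  cmp <- .coerceTable(.readTable(paths["compartments"]), .compartmentCols,
                      "compartments", .tableFiles["compartments"])
  sp <- .coerceTable(.readTable(paths["species"]), .speciesCols,
                     "species", .tableFiles["species"])
  rl <- .coerceTable(.readTable(paths["ratelaws"]), .ratelawCols,
                     "ratelaws", .tableFiles["ratelaws"])
  gn <- .coerceTable(.readTable(paths["genes"]), .geneCols,
                     "genes", .tableFiles["genes"])
  om <- .coerceTable(.readTable(paths["omics"]), .omicsCols,
                     "omics", .tableFiles["omics"])
  tr <- if (file.exists(paths["tars"])) {
    .coerceTable(.readTable(paths["tars"]), .tarCols, "tars",
                 .tableFiles["tars"])
  } else .emptyTable(.tarCols)
  m <- new("MechModel", compartments = cmp, species = sp, genes = gn,
           ratelaws = rl, tars = tr, omics = om,
           provenance = sprintf("read %d genes, %d species, %d ratelaws, %d TARs from %s",
                                nrow(gn), nrow(sp), nrow(rl), nrow(tr), dir))
  ct <- modelCounts(m)
  message(sprintf("read model: %d genes, %d species, %d ratelaws, %d TARs, %d parameters",
                  ct["genes"], ct["species"], ct["ratelaws"], ct["tars"],
                  ct["parameters"]))
  m
}

.writeTable <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- vapply(out[[nm]], function(x)
        if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE,
                                       trim = TRUE), character(1))
      ## very small/large magnitudes round-trip better in scientific notation
      sci <- !is.na(out[[nm]]) & out[[nm]] != 0 &
        (abs(out[[nm]]) < 1e-4 | abs(out[[nm]]) >= 1e15)
      v[sci] <- vapply(out[[nm]][sci], function(x)
        format(x, digits = 17, scientific = TRUE, trim = TRUE), character(1))
      out[[nm]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Write a mechanistic model as tab-delimited tables
#'
#' Writes the six model tables into a directory in the same dialect that
#' [readModelTables()] reads; the round trip reproduces the model exactly
#' (numeric values at full precision, text byte-identical).
#'
#' @param m a valid \linkS4class{MechModel}.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
writeModelTables <- function(m, dir) {
  stopifnot(is(m, "MechModel"))
  validObject(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(compartments = m@compartments, species = m@species,
               ratelaws = m@ratelaws, genes = m@genes, omics = m@omics,
               tars = m@tars)
  paths <- file.path(dir, .tableFiles[names(tabs)])
  for (i in seq_along(tabs)) .writeTable(tabs[[i]], paths[i])
  invisible(paths)
}
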