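.readOmicsFile <- function(path) {
  .coerceTable(.readTable(path), .omicsCols, "omics", basename(path))
}

.readDataFile <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("condition", "species", "time_h", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("data file missing columns: ", paste(miss, collapse = ", "))
  d
}

.dosesFromConfig <- function(lst) {
  if (is.null(lst) || !length(lst)) return(NULL)
  do.call(rbind, lapply(lst, function(d)
    doseSpec(d$species, as.numeric(d$concentration),
             onset = as.numeric(d$onset %||% 0))))
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}

#' Run the full expansion-to-screen pipeline
#'
#' Wires the stages end to end from a single configuration: read the base
#' model tables, load and optionally seed-filter the association network,
#' expand the model, write the expanded tables and their SBML export plus a
#' JSON expansion report, then (when calibration data are configured) fit
#' basal transcription rates and half-maximal constants, and (when readouts
#' are configured) run the knockout screen. Every JSON artifact embeds the
#' configuration hash; the pipeline is deterministic, and each stage fails
#' loudly with its name.
#'
#' @param config path to a YAML file or an equivalent named list. Keys:
#'   \code{modelDir}, \code{edges}, \code{outDir} (required); \code{seeds}
#'   (gene symbols for [filterToSeeds()]); \code{omics} (TSV path);
#'   \code{data} (fold-change TSV with condition/species/time_h/value);
#'   \code{conditions} (named list of dose lists); \code{scenario} (dose
#'   list for the knockout screen); \code{knockout} (list with
#'   \code{readouts}, optional \code{genes}, \code{hours},
#'   \code{threshold}); \code{fit} (optional \code{gridPoints},
#'   \code{gridDecades}, \code{span}, \code{hours},
#'   \code{preEquilibrateHours}); \code{selfRegulation}.
#' @return invisibly, a list with the expanded model, reports and fits.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("modelDir", "edges", "outDir"))
    if (is.null(config[[key]]))
      stop("config validation: missing required key '", key, "'")
  for (key in c("modelDir", "edges"))
    if (!file.exists(config[[key]]))
      stop("config validation: path for '", key, "' not found: ",
           config[[key]])
  if (!is.null(config$data) && is.null(config$conditions))
    stop("config validation: 'data' requires 'conditions'")
  hash <- .configHash(config)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  report <- list(config_hash = hash)

  model <- stage("read-model", readModelTables(config$modelDir))
  net <- stage("load-edges", loadAssociationEdges(config$edges))
  if (!is.null(config$seeds))
    net <- stage("filter", filterToSeeds(net, unlist(config$seeds)))
  omics <- if (!is.null(config$omics))
    stage("read-omics", .readOmicsFile(config$omics)) else NULL

  ex <- stage("expand", expandModel(
    model, net, omics,
    selfRegulation = config$selfRegulation %||% "collapse"))
  model <- ex$model
  rep <- ex$report
  report$expansion <- list(genes_added = rep@genesAdded,
                           species_added = rep@speciesAdded,
                           ratelaws_added = rep@ratelawsAdded,
                           tars_added = rep@tarsAdded,
                           defaults_used = rep@defaultsUsed,
                           dropped = rep@dropped,
                           provenance = rep@provenance)
  stage("write-model", writeModelTables(model, file.path(outDir, "model")))
  stage("export-sbml", exportSBML(model, file.path(outDir, "model.xml")))

  fits <- NULL
  if (!is.null(config$data)) {
    dat <- stage("read-data", .readDataFile(config$data))
    conditions <- lapply(config$conditions, .dosesFromConfig)
    fitCfg <- config$fit %||% list()
    fb <- stage("fit-basal", fitBasalRates(
      model, hours = fitCfg$hours %||% 48,
      gridPoints = fitCfg$gridPoints %||% 15,
      gridDecades = fitCfg$gridDecades %||% 3,
      span = fitCfg$span %||% "centered"))
    model <- fb$model
    fk <- stage("fit-KA", fitKA(
      model, dat, conditions, hours = fitCfg$hours %||% 48,
      preEquilibrateHours = fitCfg$preEquilibrateHours %||% 100,
      gridPoints = fitCfg$gridPoints %||% 15,
      gridDecades = fitCfg$gridDecades %||% 3,
      span = fitCfg$span %||% "centered"))
    model <- fk$model
    fits <- list(basal = fb$fits, KA = fk$fits)
    report$fits <- list(basal = fitTable(fb$fits), KA = fitTable(fk$fits))
    stage("write-fitted-model",
          writeModelTables(model, file.path(outDir, "model_fitted")))
    jsonlite::write_json(
      c(list(config_hash = hash),
        lapply(fits, function(f) list(table = fitTable(f),
                                      profiles = fitProfiles(f)))),
      file.path(outDir, "fits.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }

  screen <- NULL
  if (!is.null(config$knockout)) {
    ko <- config$knockout
    screen <- stage("knockout", screenKnockouts(
      model, genes = if (!is.null(ko$genes)) unlist(ko$genes) else NULL,
      readouts = unlist(ko$readouts),
      doses = .dosesFromConfig(config$scenario),
      hours = ko$hours %||% 48,
      preEquilibrateHours = ko$preEquilibrateHours %||% 0,
      threshold = ko$threshold %||% 0.05))
    report$knockout <- screenTable(screen)
    jsonlite::write_json(list(config_hash = hash,
                              threshold = screen@threshold,
                              table = screenTable(screen)),
                         file.path(outDir, "ko_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(model = model, report = ex$report, fits = fits,
                 screen = screen, configHash = hash))
}
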