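## Avogadro's number (CODATA exact value), molecules per mole.
.AVOGADRO <- 6.02214076e23

## Canonical key for an unordered gene pair.
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

## Normalize a gene symbol: trim whitespace, uppercase, optional alias map.
.normSymbol <- function(x, aliases = NULL) {
  x <- toupper(trimws(x))
  if (!is.null(aliases) && length(aliases)) {
    nm <- toupper(trimws(names(aliases)))
    val <- toupper(trimws(unname(aliases)))
    hit <- match(x, nm)
    x[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  x
}

## Parse a " + "-separated species list with optional stoichiometry prefix,
## e.g. "A + 2 B" -> c(A = 1, B = 2). Empty string -> empty vector.
.parseSpeciesList <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(setNames(numeric(0), character(0)))
  terms <- strsplit(x, "+", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (!nzchar(tm)) next
    m <- regmatches(tm, regexec("^([0-9.]+)\\s+(\\S+)$", tm))[[1]]
    if (length(m) == 3) {
      out[m[3]] <- unname(out[m[3]] %||% 0) + as.numeric(m[2])
    } else {
      out[tm] <- unname(out[tm] %||% 0) + 1
    }
  }
  out[is.na(out)] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

## Parse "k1=0.1;k2=2e-3" into a named numeric vector.
.parseParams <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(setNames(numeric(0), character(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

.formatParams <- function(v) {
  if (!length(v)) return("")
  paste(sprintf("%s=%s", names(v), vapply(v, format, character(1),
                                          digits = 17)), collapse = ";")
}

## Run code with a locally seeded RNG, restoring global RNG state afterwards.
.withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Sanitize identifiers for SBML (SId grammar). Returns the sanitized vector
## with a "mapping" attribute holding any changed names.
.sanitizeId <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- grepl("^[0-9]", out)
  out[bad] <- paste0("_", out[bad])
  changed <- which(out != x)
  map <- data.frame(original = x[changed], sanitized = out[changed],
                    stringsAsFactors = FALSE)
  attr(out, "mapping") <- map
  out
}

.num <- function(x) {
  suppressWarnings(as.numeric(x))
}

## Merge new rows into a model table keeping canonical column order.
.bindRows <- function(df, new) {
  for (nm in setdiff(names(df), names(new))) new[[nm]] <- NA
  rbind(df, new[, names(df), drop = FALSE])
}
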