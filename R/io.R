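## Readers and writers for the plain-text interchange formats: beta matrices
## (CSV/TSV, probes in rows), clock coefficient tables, probe lists, sample
## annotation and reference means.  Readers validate rather than coerce:
## duplicate IDs and non-numeric cells are hard errors.

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a beta-value matrix
#'
#' Expects CSV or TSV with probe IDs in the first column and one column per
#' sample.  The delimiter is sniffed from the first line unless given.
#' Empty cells and \code{NA} parse as missing (never as 0); duplicate probe
#' IDs or non-numeric cells are errors naming the offending location.
#'
#' @param path file path.
#' @param sep field delimiter, or \code{NULL} to sniff.
#' @param annotation optional sample annotation passed to
#'   \code{\link{BetaMatrix}}.
#' @param clipTolerance see \code{\link{BetaMatrix}}.
#' @return a \linkS4class{BetaMatrix}.
#' @export
readBetaMatrix <- function(path, sep = NULL, annotation = NULL,
                           clipTolerance = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .sniffSep(path)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("NA", ""))
  if (ncol(raw) < 2L)
    stop("beta matrix needs a probe-ID column plus at least one sample",
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probe IDs in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  badCell <- is.na(num) & !is.na(vals)
  if (any(badCell)) {
    idx <- which(badCell, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric beta value '%s' at probe '%s', sample '%s'",
                 vals[idx[1L], idx[2L]], ids[idx[1L]],
                 colnames(raw)[-1L][idx[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  BetaMatrix(num, annotation = annotation, clipTolerance = clipTolerance)
}

#' Write a beta-value matrix
#'
#' @param betas a \linkS4class{BetaMatrix}.
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(betas, path, sep = ",") {
  stopifnot(is(betas, "BetaMatrix"))
  b <- assay(betas, "beta")
  ## 17 significant digits so values survive the text round trip exactly
  txt <- matrix(.fmtNum(b), nrow(b), ncol(b), dimnames = dimnames(b))
  df <- data.frame(probe_id = rownames(b),
                   as.data.frame(txt, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Shortest decimal representation that round-trips a double exactly.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a clock coefficient table
#'
#' Accepts a two-column table (header \code{probe_id,weight}) or the column
#' layouts of the published Horvath (\code{CpGmarker,CoefficientTraining})
#' and Hannum (\code{Marker,Coefficient}) supplementary tables; other
#' layouts can be mapped explicitly with \code{probeColumn} /
#' \code{weightColumn}.  The intercept is carried as a row whose probe ID is
#' \code{(Intercept)}; a missing intercept row is an error for
#' \code{"horvath"} clocks and defaults to 0 with a warning for
#' \code{"identity"} clocks.
#'
#' @param path file path (CSV or TSV; delimiter sniffed).
#' @param transform \code{"horvath"} or \code{"identity"}.
#' @param adultAge knee of the age transform for \code{"horvath"} clocks.
#' @param name clock label (default: the file base name).
#' @param probeColumn,weightColumn optional explicit column names.
#' @return a \linkS4class{ClockDefinition}.
#' @export
readClock <- function(path, transform = c("horvath", "identity"),
                      adultAge = 20, name = NULL,
                      probeColumn = NULL, weightColumn = NULL) {
  transform <- match.arg(transform)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.csv(path, sep = .sniffSep(path), check.names = FALSE,
                  stringsAsFactors = FALSE)
  probeCands <- c(probeColumn, "probe_id", "CpGmarker", "Marker", "ID")
  weightCands <- c(weightColumn, "weight", "CoefficientTraining",
                   "Coefficient")
  pc <- intersect(probeCands, names(tab))
  wc <- intersect(weightCands, names(tab))
  if (!length(pc) || !length(wc))
    stop("cannot find probe/weight columns in ", path,
         " (have: ", paste(names(tab), collapse = ", "), ")", call. = FALSE)
  ids <- as.character(tab[[pc[1L]]])
  w <- as.numeric(tab[[wc[1L]]])
  isInt <- ids == "(Intercept)"
  intercept <- 0
  if (any(isInt)) {
    intercept <- w[isInt][1L]
  } else if (identical(transform, "horvath")) {
    stop("clock file ", path, " has no '(Intercept)' row, required for a ",
         "horvath-transform clock", call. = FALSE)
  } else {
    warning("no '(Intercept)' row in ", path, "; intercept defaults to 0",
            call. = FALSE)
  }
  ids <- ids[!isInt]; w <- w[!isInt]
  if (anyDuplicated(ids))
    stop("duplicate probe IDs in clock file ", path, call. = FALSE)
  if (anyNA(w))
    stop("non-numeric weight(s) in clock file ", path, call. = FALSE)
  ClockDefinition(name, setNames(w, ids), intercept = intercept,
                  transform = transform, adultAge = adultAge)
}

#' Write a clock coefficient table
#'
#' Two-column CSV (\code{probe_id,weight}) with the intercept as an
#' \code{(Intercept)} row; round-trips through \code{\link{readClock}}.
#'
#' @param clock a \linkS4class{ClockDefinition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClock <- function(clock, path) {
  stopifnot(is(clock, "ClockDefinition"))
  df <- data.frame(
    probe_id = c("(Intercept)", clockProbes(clock)),
    weight = .fmtNum(c(clockIntercept(clock), unname(clockWeights(clock)))),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe list
#'
#' Plain text, one probe ID per line; blank lines and \code{#} comments are
#' skipped.
#'
#' @param path file path.
#' @return character vector of probe IDs.
#' @export
readProbeList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines)]
  if (anyDuplicated(ids))
    stop("duplicate probe IDs in ", path, call. = FALSE)
  ids
}

#' Read per-probe reference means
#'
#' CSV with header \code{probe_id,mean_beta}; values must lie in [0, 1].
#'
#' @param path file path.
#' @return named numeric vector of reference mean betas.
#' @export
readReferenceMeans <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, sep = .sniffSep(path), stringsAsFactors = FALSE)
  need <- c("probe_id", "mean_beta")
  if (!all(need %in% names(tab)))
    stop("reference means file needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  rm <- setNames(as.numeric(tab$mean_beta), as.character(tab$probe_id))
  if (anyDuplicated(names(rm)))
    stop("duplicate probe IDs in ", path, call. = FALSE)
  if (anyNA(rm) || any(rm < 0 | rm > 1))
    stop("reference means must lie in [0, 1]", call. = FALSE)
  rm
}

#' Write per-probe reference means
#'
#' @param referenceMeans named numeric vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceMeans <- function(referenceMeans, path) {
  df <- data.frame(probe_id = names(referenceMeans),
                   mean_beta = .fmtNum(unname(referenceMeans)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' CSV/TSV with a \code{sample_id} column and optional \code{age},
#' \code{sex}, \code{platform}, \code{dataset} columns (missing columns
#' become \code{NA}).
#'
#' @param path file path.
#' @return data frame suitable for \code{\link{BetaMatrix}}'s
#'   \code{annotation} argument.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, sep = .sniffSep(path), stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab))
    stop("annotation file needs a 'sample_id' column", call. = FALSE)
  for (col in c("age", "sex", "platform", "dataset"))
    if (!col %in% names(tab)) tab[[col]] <- NA
  tab$age <- as.numeric(tab$age)
  tab[, c("sample_id", "age", "sex", "platform", "dataset")]
}

#' Write per-sample DNAm ages
#'
#' CSV with ages and scores rounded to 4 decimal places (full precision is
#' preserved in JSON summaries).
#'
#' @param ages a \linkS4class{ClockAges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClockAges <- function(ages, path) {
  stopifnot(is(ages, "ClockAges"))
  df <- ages@results
  df$dnam_age <- round(df$dnam_age, 4L)
  df$transformed_score <- round(df$transformed_score, 4L)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample DNAm ages written by writeClockAges
#'
#' @param path file path.
#' @param clockName,imputationPolicy provenance labels to attach (defaults
#'   \code{"unknown"}).
#' @return a \linkS4class{ClockAges}.
#' @export
readClockAges <- function(path, clockName = "unknown",
                          imputationPolicy = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dnam_age")
  if (!all(need %in% names(df)))
    stop("DNAm-age file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"transformed_score" %in% names(df)) df$transformed_score <- NA_real_
  if (!"n_probes_used" %in% names(df)) df$n_probes_used <- NA_integer_
  if (!"n_probes_imputed" %in% names(df)) df$n_probes_imputed <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  new("ClockAges", results = df, clockName = clockName,
      imputationPolicy = imputationPolicy, probesImputed = character(0))
}

#' Write a comparison report as CSV tables plus a JSON summary
#'
#' Emits \code{<prefix>_overall.csv}, \code{<prefix>_by_dataset.csv},
#' \code{<prefix>_by_age_bin.csv}, \code{<prefix>_deviations.csv} and a
#' machine-readable \code{<prefix>_summary.json} (full precision).
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"comparison"}).
#' @return character vector of the paths written, invisibly.
#' @export
writeComparisonReport <- function(report, dir, prefix = "comparison") {
  stopifnot(is(report, "ComparisonReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
    c("overall.csv", "by_dataset.csv", "by_age_bin.csv", "deviations.csv",
      "summary.json")))
  write.csv(report@overall, paths[1L], row.names = FALSE)
  write.csv(report@byDataset, paths[2L], row.names = FALSE)
  write.csv(report@byAgeBin, paths[3L], row.names = FALSE)
  write.csv(report@deviations, paths[4L], row.names = FALSE)
  write_json(list(overall = report@overall, by_dataset = report@byDataset,
                  by_age_bin = report@byAgeBin, bin_width = report@binWidth),
             paths[5L], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Paths of the bundled EPIC-missing probe lists
#'
#' The package ships plain-text lists of the clock CpGs absent from the
#' Illumina MethylationEPIC (850k) manifest: 17 of the 353 Horvath-clock
#' probes and 6 of the 71 Hannum-clock probes.
#'
#' @param clock \code{"horvath"} or \code{"hannum"}.
#' @return path to the probe-list file.
#' @examples
#' length(readProbeList(epicMissingProbesFile("horvath")))  # 17
#' @export
epicMissingProbesFile <- function(clock = c("horvath", "hannum")) {
  clock <- match.arg(clock)
  system.file("extdata", paste0("epic_missing_", clock, ".txt"),
              package = "dnamclock", mustWork = TRUE)
}
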