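#' Construct a BetaMatrix
#'
#' Wraps a probes-by-samples matrix of methylation fractions in a
#' \linkS4class{SummarizedExperiment}-backed container with validation.
#' Values outside [0, 1] by at most \code{clipTolerance} (rounding spill, as
#' occasionally found in public series matrices) are clipped; larger
#' excursions are rejected.  \code{NA} entries denote missing measurements.
#'
#' @param values numeric matrix, probes in rows (unique rownames), samples in
#'   columns (unique colnames); entries in [0, 1] or \code{NA}.
#' @param annotation optional per-sample annotation: a data frame with a
#'   \code{sample_id} column covering every sample and optional columns
#'   \code{age} (years, \code{NA} allowed), \code{sex} (\code{"female"},
#'   \code{"male"} or \code{NA}), \code{platform} (\code{"27k"},
#'   \code{"450k"}, \code{"850k"}, \code{"synthetic"} or \code{NA}) and
#'   \code{dataset} (free label).
#' @param clipTolerance values in \code{[-clipTolerance, 1 + clipTolerance]}
#'   are clipped into [0, 1]; beyond that an error is thrown.
#' @return a \linkS4class{BetaMatrix}.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' bm <- BetaMatrix(m)
#' betaValues(bm)
#' @export
BetaMatrix <- function(values, annotation = NULL, clipTolerance = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs", call. = FALSE)
  bad <- !is.na(values) &
    (values < -clipTolerance | values > 1 + clipTolerance)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "beta value out of [0, 1] beyond tolerance at probe '%s', sample '%s': %g",
      rownames(values)[idx[1L]], colnames(values)[idx[2L]],
      values[idx[1L], idx[2L]]), call. = FALSE)
  }
  values[!is.na(values) & values < 0] <- 0
  values[!is.na(values) & values > 1] <- 1

  cd <- .annotationColData(annotation, colnames(values))
  new("BetaMatrix",
      SummarizedExperiment(assays = list(beta = values), colData = cd))
}

## Validates and aligns sample annotation to the sample order of the matrix.
.annotationColData <- function(annotation, sampleIDs) {
  cols <- c("age", "sex", "platform", "dataset")
  if (is.null(annotation)) {
    n <- length(sampleIDs)
    cd <- DataFrame(age = rep(NA_real_, n), sex = rep(NA_character_, n),
                    platform = rep(NA_character_, n),
                    dataset = rep(NA_character_, n),
                    row.names = sampleIDs)
    return(cd)
  }
  annotation <- as.data.frame(annotation)
  if (!"sample_id" %in% names(annotation))
    stop("annotation needs a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample IDs in annotation", call. = FALSE)
  missing <- setdiff(sampleIDs, annotation$sample_id)
  if (length(missing))
    stop("annotation does not cover samples: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  idx <- match(sampleIDs, annotation$sample_id)
  get <- function(col, default) {
    if (col %in% names(annotation)) annotation[[col]][idx] else default
  }
  age <- as.numeric(get("age", NA_real_))
  if (any(age < 0, na.rm = TRUE))
    stop("annotation ages must be non-negative", call. = FALSE)
  sex <- as.character(get("sex", NA_character_))
  badSex <- !is.na(sex) & !sex %in% c("female", "male")
  if (any(badSex))
    stop("annotation 'sex' must be \"female\", \"male\" or NA", call. = FALSE)
  platform <- as.character(get("platform", NA_character_))
  badPlat <- !is.na(platform) & !platform %in% c("27k", "450k", "850k", "synthetic")
  if (any(badPlat))
    stop("annotation 'platform' must be one of \"27k\", \"450k\", \"850k\", \"synthetic\" or NA",
         call. = FALSE)
  DataFrame(age = age, sex = sex, platform = platform,
            dataset = as.character(get("dataset", NA_character_)),
            row.names = sampleIDs)
}

#' Accessors for BetaMatrix objects
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @return \code{betaValues}: the numeric probes-by-samples matrix;
#'   \code{probeIDs} / \code{sampleIDs}: the identifier vectors;
#'   \code{sampleAnnotation}: a data frame with columns \code{sample_id},
#'   \code{age}, \code{sex}, \code{platform}, \code{dataset}.
#' @name BetaMatrix-accessors
NULL

#' @rdname BetaMatrix-accessors
setMethod("betaValues", "BetaMatrix", function(x) assay(x, "beta"))

#' @rdname BetaMatrix-accessors
setMethod("probeIDs", "BetaMatrix", function(x) rownames(x))

#' @rdname BetaMatrix-accessors
setMethod("sampleIDs", "BetaMatrix", function(x) colnames(x))

#' @rdname BetaMatrix-accessors
setMethod("sampleAnnotation", "BetaMatrix", function(x) {
  cd <- as.data.frame(colData(x))
  data.frame(sample_id = colnames(x), cd, row.names = NULL,
             stringsAsFactors = FALSE)
})

setMethod("show", "BetaMatrix", function(object) {
  b <- assay(object, "beta")
  cat("BetaMatrix: ", nrow(object), " probes x ", ncol(object), " samples\n",
      sep = "")
  nNA <- sum(is.na(b))
  if (nNA)
    cat("  missing cells: ", nNA, sprintf(" (%.1f%%)", 100 * nNA / length(b)),
        "\n", sep = "")
  ages <- colData(object)$age
  if (!all(is.na(ages)))
    cat("  ages: ", format(min(ages, na.rm = TRUE)), "-",
        format(max(ages, na.rm = TRUE)), " y (",
        sum(!is.na(ages)), " known)\n", sep = "")
  invisible(NULL)
})

#' Remove probes from a beta matrix
#'
#' Drops the listed probes, emulating a platform that does not assay them
#' (e.g. restricting 450k data to the EPIC manifest).  IDs not present in the
#' matrix are ignored with a warning; dropping every probe is an error.  The
#' input object is not modified and the sample set is unchanged.
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @param probes character vector of probe IDs to remove.
#' @param ... unused.
#' @return a \linkS4class{BetaMatrix} without the listed probes.
#' @examples
#' m <- matrix(runif(6), 3, dimnames = list(paste0("cg", 1:3), c("a", "b")))
#' maskProbes(BetaMatrix(m), "cg2")
#' @rdname maskProbes
#' @export
setMethod("maskProbes", "BetaMatrix", function(x, probes, ...) {
  probes <- as.character(probes)
  unknown <- setdiff(probes, rownames(x))
  if (length(unknown))
    warning("ignoring ", length(unknown),
            " probe ID(s) not present in the matrix: ",
            paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  keep <- setdiff(rownames(x), probes)
  if (!length(keep))
    stop("masking would remove every probe", call. = FALSE)
  x[keep, ]
})
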