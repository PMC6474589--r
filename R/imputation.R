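#' Construct an imputation policy
#'
#' Declares how clock probes that are absent from a beta matrix -- or present
#' with missing cells -- are resolved before scoring.  Probes that are
#' present but \code{NA} are treated identically to absent probes.
#'
#' \describe{
#'   \item{\code{reference_mean}}{each missing value is replaced by the
#'     probe's mean beta in a reference ("gold standard") cohort, the
#'     behaviour of the online Horvath calculator.  Requires
#'     \code{referenceMeans}.}
#'   \item{\code{cohort_mean}}{missing cells are replaced by the probe's
#'     observed mean within the cohort itself; cannot resolve fully absent
#'     probes.}
#'   \item{\code{knn}}{k-nearest-neighbour imputation across probe rows, the
#'     Hannum-style workflow (see \code{\link{imputeKNN}}).  Cannot resolve
#'     fully absent probes.}
#'   \item{\code{constant}}{every missing value is set to
#'     \code{constantValue}.}
#'   \item{\code{none}}{no imputation; any missing clock probe is an error.}
#' }
#'
#' @param method imputation method (see details).
#' @param k number of neighbours for \code{"knn"} (default 10, the
#'   conventional default of kNN expression/methylation imputation).
#' @param constantValue fill value in [0, 1] for \code{"constant"}.
#' @param referenceMeans named numeric vector of per-probe reference mean
#'   betas for \code{"reference_mean"} (see \code{\link{readReferenceMeans}}).
#' @return an \linkS4class{ImputationPolicy}.
#' @examples
#' imputationPolicy("reference_mean", referenceMeans = c(cg1 = 0.6))
#' imputationPolicy("knn", k = 5)
#' @export
imputationPolicy <- function(method = c("reference_mean", "cohort_mean",
                                        "knn", "constant", "none"),
                             k = 10, constantValue = NA_real_,
                             referenceMeans = NULL) {
  method <- match.arg(method)
  if (is.null(referenceMeans)) referenceMeans <- setNames(numeric(0), character(0))
  new("ImputationPolicy", method = method, k = as.numeric(k),
      constantValue = as.numeric(constantValue),
      referenceMeans = referenceMeans)
}

setMethod("show", "ImputationPolicy", function(object) {
  cat("ImputationPolicy: ", object@method, sep = "")
  if (identical(object@method, "knn"))
    cat(" (k = ", object@k, ")", sep = "")
  if (identical(object@method, "constant"))
    cat(" (value = ", object@constantValue, ")", sep = "")
  if (identical(object@method, "reference_mean"))
    cat(" (", length(object@referenceMeans), " reference probes)", sep = "")
  cat("\n")
})

#' Reference-mean imputation of missing probes
#'
#' Adds every needed probe that is absent from the matrix as a constant row
#' equal to its reference mean beta, and fills \code{NA} cells of needed
#' probes that are present.  Existing observed values are untouched.
#'
#' @param betas a \linkS4class{BetaMatrix} or numeric matrix.
#' @param neededProbes probe IDs that must be resolvable afterwards
#'   (default: probes of the matrix itself).
#' @param referenceMeans named numeric vector of reference mean betas; must
#'   cover every needed probe that has missing values.
#' @return object of the same type as \code{betas} with the needed probes
#'   filled (absent probes are appended as new rows).
#' @examples
#' m <- matrix(c(0.2, NA, 0.4, 0.5), 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' imputeReferenceMean(m, c("cg1", "cg2", "cg9"),
#'                     c(cg1 = 0.3, cg2 = 0.3, cg9 = 0.6))
#' @export
imputeReferenceMean <- function(betas, neededProbes = NULL, referenceMeans) {
  .withBetaMatrix(betas, function(m) {
    if (is.null(neededProbes)) neededProbes <- rownames(m)
    neededProbes <- as.character(neededProbes)
    if (!length(referenceMeans) || is.null(names(referenceMeans)))
      stop("'referenceMeans' must be named by probe ID", call. = FALSE)
    absent <- setdiff(neededProbes, rownames(m))
    if (length(absent)) {
      add <- matrix(NA_real_, length(absent), ncol(m),
                    dimnames = list(absent, colnames(m)))
      m <- rbind(m, add)
    }
    target <- intersect(neededProbes, rownames(m))
    hasNA <- target[rowSums(is.na(m[target, , drop = FALSE])) > 0L]
    uncovered <- setdiff(hasNA, names(referenceMeans))
    if (length(uncovered))
      stop("no reference mean for probe(s): ",
           paste(head(uncovered, 10L), collapse = ", "), call. = FALSE)
    for (p in hasNA) {
      miss <- is.na(m[p, ])
      m[p, miss] <- referenceMeans[[p]]
    }
    m
  })
}

#' Cohort-mean imputation of missing cells
#'
#' Replaces each missing cell by the probe's mean over its observed values in
#' the same matrix.  A probe with no observed value at all cannot be resolved
#' and is left as-is (it is escalated by \code{\link{applyClock}}).
#'
#' @param betas a \linkS4class{BetaMatrix} or numeric matrix.
#' @param neededProbes probe IDs to fill (default: all probes present).
#' @return object of the same type as \code{betas} with row-mean fills.
#' @export
imputeCohortMean <- function(betas, neededProbes = NULL) {
  .withBetaMatrix(betas, function(m) {
    if (is.null(neededProbes)) neededProbes <- rownames(m)
    target <- intersect(as.character(neededProbes), rownames(m))
    for (p in target) {
      row <- m[p, ]
      miss <- is.na(row)
      if (any(miss) && any(!miss))
        m[p, miss] <- mean(row[!miss])
    }
    m
  })
}

#' k-nearest-neighbour imputation across probe rows
#'
#' For each probe row with missing cells, the k nearest fully observed probe
#' rows are found by Euclidean distance computed over the columns where the
#' target row is observed, and each missing cell is filled with the unweighted
#' mean of the neighbours' values in that column -- the imputation orientation
#' of the Hannum workflow (probes as rows, neighbours are probes).
#'
#' Determinism: ties in neighbour distance are broken by probe-ID
#' lexicographic (byte) order.  If \code{k} exceeds the number of fully
#' observed candidate rows, all candidates are used with a warning.  A target
#' row with no observed cell (no basis for a distance) falls back to the
#' cohort mean, which cannot resolve it either, so it is left missing and
#' escalated downstream.
#'
#' @param betas a \linkS4class{BetaMatrix} or numeric matrix.
#' @param k number of neighbours (default 10).
#' @return object of the same type as \code{betas} with kNN fills.
#' @examples
#' m <- matrix(c(0.2, 0.2, 0.8,  0.4, 0.4, 0.1,  0.6, NA, 0.3), 3,
#'             byrow = TRUE,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:3)))
#' imputeKNN(m, k = 1)
#' @export
imputeKNN <- function(betas, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("'k' must be a positive integer", call. = FALSE)
  .withBetaMatrix(betas, function(m) {
    if (nrow(m) < k + 1)
      stop("kNN imputation needs at least k + 1 probes", call. = FALSE)
    .knnImputeMatrix(m, as.integer(k))
  })
}

## Core kNN fill on a plain matrix; rows = probes.  Neighbour pool is the set
## of fully observed rows, so the k = n_complete limit reproduces the mean of
## all complete rows per column.
.knnImputeMatrix <- function(m, k) {
  miss <- is.na(m)
  if (!any(miss)) return(m)
  complete <- rownames(m)[rowSums(miss) == 0L]
  targets <- rownames(m)[rowSums(miss) > 0L]
  warned <- FALSE
  for (p in targets) {
    row <- m[p, ]
    obs <- which(!is.na(row))
    if (!length(obs) || !length(complete)) {
      ## no usable neighbours: cohort-mean fallback over observed cells
      if (length(obs)) m[p, is.na(m[p, ])] <- mean(row[obs])
      next
    }
    cand <- m[complete, obs, drop = FALSE]
    d <- sqrt(rowSums((cand - rep(row[obs], each = nrow(cand)))^2))
    kk <- min(k, length(complete))
    if (kk < k && !warned) {
      warning("k = ", k, " exceeds the ", length(complete),
              " fully observed candidate probes; using all of them",
              call. = FALSE)
      warned <- TRUE
    }
    ord <- order(d, complete, method = "radix")
    nb <- complete[ord[seq_len(kk)]]
    fill <- which(is.na(m[p, ]))
    m[p, fill] <- colMeans(m[nb, fill, drop = FALSE])
  }
  m
}

## Applies a policy to a numeric matrix restricted to clock probes; used by
## applyClock.  Returns the (possibly still incomplete) matrix.
.applyImputation <- function(m, policy) {
  switch(policy@method,
    none = m,
    reference_mean = imputeReferenceMean(m, rownames(m), policy@referenceMeans),
    cohort_mean = imputeCohortMean(m),
    knn = .knnImputeMatrix(m, as.integer(policy@k)),
    constant = { m[is.na(m)] <- policy@constantValue; m })
}

## Run `fun` on the underlying matrix, preserving BetaMatrix-ness (and
## annotation) of the input.
.withBetaMatrix <- function(betas, fun) {
  if (is(betas, "BetaMatrix")) {
    m <- fun(assay(betas, "beta"))
    ann <- sampleAnnotation(betas)
    BetaMatrix(m, annotation = ann)
  } else if (is.matrix(betas) && is.numeric(betas)) {
    fun(betas)
  } else {
    stop("'betas' must be a BetaMatrix or a numeric matrix", call. = FALSE)
  }
}
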