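## Independent oracles used across the suite.  These re-derive expected
## values from first principles (explicit loops, closed-form normal
## equations) and deliberately share no code with the implementation paths
## they check.

## Brute-force kNN imputation over probe rows: for every missing cell, rank
## all fully observed rows by Euclidean distance over the target's observed
## columns, break ties by picking the byte-order-smallest probe ID first,
## and average the k nearest neighbours' values in that column.
bruteKNN <- function(m, k) {
  out <- m
  complete <- rownames(m)[apply(!is.na(m), 1L, all)]
  for (r in rownames(m)) {
    missCols <- which(is.na(m[r, ]))
    if (!length(missCols)) next
    obsCols <- which(!is.na(m[r, ]))
    if (!length(obsCols) || !length(complete)) {
      if (length(obsCols)) out[r, missCols] <- mean(m[r, obsCols])
      next
    }
    d <- vapply(complete, function(q)
      sqrt(sum((m[q, obsCols] - m[r, obsCols])^2)), numeric(1))
    ## iterative selection with explicit tie-breaking
    nb <- character(0)
    cand <- complete
    dd <- d
    for (i in seq_len(min(k, length(complete)))) {
      tied <- cand[dd == min(dd)]
      pick <- sort(tied, method = "radix")[1L]
      nb <- c(nb, pick)
      keep <- cand != pick
      cand <- cand[keep]
      dd <- dd[keep]
    }
    for (cc in missCols)
      out[r, cc] <- mean(m[nb, cc])
  }
  out
}

## Textbook OLS via the normal equations (QR-free, lm-free).
olsClosedForm <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- as.vector(y - X %*% beta)
  n <- length(y)
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(estimate = as.vector(beta), se = as.vector(se), residuals = resid)
}

## Random beta matrix with missing cells, for imputation tests.
randomBetaMatrix <- function(nProbes, nSamples, naFrac = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nProbes * nSamples, 0.05, 0.95), nProbes, nSamples,
              dimnames = list(sprintf("cg%03d", seq_len(nProbes)),
                              sprintf("s%02d", seq_len(nSamples))))
  if (naFrac > 0) {
    idx <- which(runif(length(m)) < naFrac)
    m[idx] <- NA_real_
  }
  m
}

## The age transform written out independently, for oracle arithmetic.
oracleTransform <- function(a, A = 20) {
  ifelse(a <= A, log(a + 1) - log(A + 1), (a - A) / (A + 1))
}
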