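# Independent reference implementations used as oracles.

# Full-matrix affine-gap DP (Gotoh) in plain R, with the same documented tie
# preferences as the production aligner (M over X over Y among diagonal
# predecessors; gap extension preferred on ties; the final cell of a global
# alignment prefers gap states so trailing gaps are terminal).
oracleAlign <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2,
                        mode = c("global", "local")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tbM <- matrix(0L, n + 1, m + 1)
  tbX <- matrix(0L, n + 1, m + 1)
  tbY <- matrix(0L, n + 1, m + 1)
  if (mode == "global") {
    M[1, 1] <- 0
    for (j in 2:(m + 1)) {
      Y[1, j] <- -(go + (j - 1) * ge)
      tbY[1, j] <- if (j == 2) 0L else 1L
    }
    for (i in 2:(n + 1)) {
      X[i, 1] <- -(go + (i - 1) * ge)
      tbX[i, 1] <- if (i == 2) 0L else 1L
    }
  }
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      vm <- M[i - 1, j - 1]; t <- 0L
      if (X[i - 1, j - 1] > vm) { vm <- X[i - 1, j - 1]; t <- 1L }
      if (Y[i - 1, j - 1] > vm) { vm <- Y[i - 1, j - 1]; t <- 2L }
      if (mode == "local" && 0 > vm) { vm <- 0; t <- 3L }
      M[i, j] <- s + vm; tbM[i, j] <- t
      xo <- M[i - 1, j] - go - ge; xe <- X[i - 1, j] - ge
      if (xe >= xo) { X[i, j] <- xe; tbX[i, j] <- 1L }
      else { X[i, j] <- xo; tbX[i, j] <- 0L }
      yo <- M[i, j - 1] - go - ge; ye <- Y[i, j - 1] - ge
      if (ye >= yo) { Y[i, j] <- ye; tbY[i, j] <- 1L }
      else { Y[i, j] <- yo; tbY[i, j] <- 0L }
      if (mode == "local" && M[i, j] > best) {
        best <- M[i, j]; bi <- i; bj <- j
      }
    }
  }
  if (mode == "global") {
    best <- M[n + 1, m + 1]; state <- 0L
    if (X[n + 1, m + 1] >= best) { best <- X[n + 1, m + 1]; state <- 1L }
    if (Y[n + 1, m + 1] >= best) { best <- Y[n + 1, m + 1]; state <- 2L }
    bi <- n + 1; bj <- m + 1
  } else {
    if (bi == 0) return(list(score = 0, identity = 0, matches = 0,
                             columns = 0))
    state <- 0L
  }
  # traceback collecting aligned columns
  qa <- integer(0); qb <- integer(0)
  i <- bi; j <- bj
  while (TRUE) {
    if (i == 1 && j == 1) break
    if (state == 0L) {
      qa <- c(i - 1, qa); qb <- c(j - 1, qb)
      t <- tbM[i, j]; i <- i - 1; j <- j - 1
      if (t == 3L) break
      if (mode == "local" && (i == 1 || j == 1)) break
      state <- t
    } else if (state == 1L) {
      qa <- c(i - 1, qa); qb <- c(NA, qb)
      t <- tbX[i, j]; i <- i - 1
      state <- if (t == 0L) 0L else 1L
    } else {
      qa <- c(NA, qa); qb <- c(j - 1, qb)
      t <- tbY[i, j]; j <- j - 1
      state <- if (t == 0L) 0L else 2L
    }
  }
  pairs <- which(!is.na(qa) & !is.na(qb))
  if (length(pairs) == 0)
    return(list(score = best, identity = 0, matches = 0, columns = 0))
  keep <- seq(min(pairs), max(pairs))
  matches <- sum(!is.na(qa[keep]) & !is.na(qb[keep]) &
                   A[ifelse(is.na(qa[keep]), 1, qa[keep])] ==
                   B[ifelse(is.na(qb[keep]), 1, qb[keep])] &
                   !is.na(qa[keep]) & !is.na(qb[keep]))
  list(score = best, identity = matches / length(keep),
       matches = matches, columns = length(keep))
}

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive hypothesis enumeration for the min/max mislabel bound: under
# "taxon t carries the correct label", the error count is n - count(t); the
# bracket spans the hypotheses with the largest (min) and smallest (max)
# group.
oracleMinMax <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (length(counts) <= 1) return(c(min = 0L, max = 0L))
  errs <- n - counts
  c(min = as.integer(min(errs[counts == max(counts)])),
    max = as.integer(max(errs[counts == min(counts)])))
}

# all multisets of positive taxon counts with total n over at most k taxa
allCountMultisets <- function(n, k) {
  out <- list()
  recurse <- function(rest, maxPart, acc) {
    if (rest == 0) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    if (length(acc) == k) return()
    for (p in seq(min(rest, maxPart), 1)) recurse(rest - p, p, c(acc, p))
  }
  recurse(n, n, integer(0))
  out
}
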