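#' Alignment scoring scheme with Karlin-Altschul statistics
#'
#' Bundles a substitution matrix, affine gap costs and the ungapped
#' Karlin-Altschul parameters \eqn{\lambda} and \eqn{K} used to convert raw
#' local-alignment scores into bit scores and E-values. \eqn{\lambda} is
#' solved numerically from the identity
#' \deqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}
#' under the scheme's background letter composition; \eqn{K} is not estimated
#' and defaults to the customary value for the alphabet.
#'
#' @slot alphabet `"nucleotide"` or `"amino-acid"`.
#' @slot match,mismatch Match reward and mismatch penalty (nucleotide mode;
#'   `NA` in amino-acid mode).
#' @slot gapOpen,gapExtend Non-negative gap costs; a gap of length L costs
#'   `gapOpen + L * gapExtend`.
#' @slot submat Square substitution matrix with letter dimnames.
#' @slot background Background letter probabilities (zero for letters such as
#'   `N` or `X` that are excluded from the statistics).
#' @slot lambda,K Karlin-Altschul parameters (lambda in nats per score unit).
#'
#' @seealso [scoringScheme()], [bitScore()], [eValue()]
#' @export
setClass("ScoringScheme",
  representation(alphabet = "character", match = "numeric",
                 mismatch = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", submat = "matrix",
                 background = "numeric", lambda = "numeric", K = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@alphabet %in% c("nucleotide", "amino-acid"))
      msg <- c(msg, "alphabet must be 'nucleotide' or 'amino-acid'")
    if (object@gapOpen < 0 || object@gapExtend < 0)
      msg <- c(msg, "gap costs must be non-negative")
    p <- object@background
    if (abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, "background probabilities must sum to 1")
    if (length(msg) == 0) {
      use <- p > 0
      s <- object@submat[use, use, drop = FALSE]
      pp <- p[use]
      ka <- sum(outer(pp, pp) * exp(object@lambda * s))
      if (abs(ka - 1) > 1e-6)
        msg <- c(msg, sprintf(
          "lambda does not satisfy the Karlin-Altschul identity (residual %.2e)",
          ka - 1))
    }
    if (length(msg)) msg else TRUE
  })

#' Solve the ungapped Karlin-Altschul lambda
#'
#' Finds the unique positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}. Requires a negative
#' expected score and at least one positive score, the usual conditions for
#' local-alignment statistics to exist.
#'
#' @param submat Square substitution matrix.
#' @param background Background probabilities over the matrix letters
#'   (letters with probability 0 are ignored).
#' @return The value of lambda in nats per score unit.
#' @examples
#' m <- matrix(-3, 4, 4); diag(m) <- 2
#' karlinLambda(m, rep(0.25, 4))
#' @export
karlinLambda <- function(submat, background) {
  use <- background > 0
  s <- submat[use, use, drop = FALSE]
  p <- background[use] / sum(background[use])
  pp <- outer(p, p)
  es <- sum(pp * s)
  if (es >= 0)
    stop("expected score is non-negative; Karlin-Altschul statistics undefined")
  if (max(s) <= 0)
    stop("no positive score in the substitution matrix")
  f <- function(lam) sum(pp * exp(lam * s)) - 1
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-10, upper), tol = 1e-12)$root
}

#' Construct a scoring scheme
#'
#' Nucleotide mode builds a match/mismatch matrix over `A C G T` plus an `N`
#' letter that mismatches everything; amino-acid mode uses BLOSUM62 (from
#' Biostrings) with a uniform background over the 20 standard residues.
#' Defaults mirror common BLASTN practice: match +2, mismatch -3, gap open 5,
#' gap extend 2, `K = 0.41` (nucleotide) or `K = 0.134` (amino acid).
#'
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param match,mismatch Nucleotide match reward / mismatch penalty.
#' @param gapOpen,gapExtend Non-negative affine gap costs.
#' @param K Karlin-Altschul K; alphabet-specific default when `NULL`.
#' @param submat Optional substitution matrix overriding the default
#'   (amino-acid mode).
#' @param background Optional background probabilities over the matrix
#'   letters.
#' @return A [ScoringScheme-class] object.
#' @examples
#' sc <- scoringScheme()
#' sc@lambda
#' @export
scoringScheme <- function(alphabet = c("nucleotide", "amino-acid"),
                          match = 2, mismatch = -3,
                          gapOpen = 5, gapExtend = 2,
                          K = NULL, submat = NULL, background = NULL) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    letters4 <- c("A", "C", "G", "T", "N")
    if (is.null(submat)) {
      submat <- matrix(mismatch, 5, 5, dimnames = list(letters4, letters4))
      diag(submat) <- match
      submat["N", ] <- mismatch
      submat[, "N"] <- mismatch
    }
    if (is.null(background))
      background <- setNames(c(rep(0.25, 4), 0), rownames(submat))
    if (is.null(K)) K <- 0.41
  } else {
    if (is.null(submat)) submat <- .blosum62()
    if (is.null(background)) {
      aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
      background <- setNames(rep(0, nrow(submat)), rownames(submat))
      background[aa] <- 1 / length(aa)
    }
    if (is.null(K)) K <- 0.134
    match <- NA_real_
    mismatch <- NA_real_
  }
  lambda <- karlinLambda(submat, background)
  new("ScoringScheme", alphabet = alphabet, match = match,
      mismatch = mismatch, gapOpen = gapOpen, gapExtend = gapExtend,
      submat = submat, background = background, lambda = lambda, K = K)
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme (%s): ", object@alphabet))
  if (object@alphabet == "nucleotide")
    cat(sprintf("match %+g / mismatch %+g, ", object@match, object@mismatch))
  else
    cat("BLOSUM62, ")
  cat(sprintf("gap %g/%g, lambda = %.4f, K = %.3f\n",
              object@gapOpen, object@gapExtend, object@lambda, object@K))
})

#' Convert a raw alignment score to a bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw Raw alignment score(s).
#' @param scheme A [ScoringScheme-class].
#' @return Numeric bit score(s).
#' @export
bitScore <- function(raw, scheme) {
  (scheme@lambda * raw - log(scheme@K)) / log(2)
}

#' Expected number of chance alignments (E-value)
#'
#' `E = K * m * n * exp(-lambda * raw)` for a search space of query length
#' `m` and subject (or panel) length `n`.
#'
#' @param raw Raw alignment score(s).
#' @param m,n Search-space lengths in scheme alphabet units.
#' @param scheme A [ScoringScheme-class].
#' @return Numeric E-value(s).
#' @export
eValue <- function(raw, m, n, scheme) {
  scheme@K * m * n * exp(-scheme@lambda * raw)
}
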