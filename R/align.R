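# Pairwise alignment wrappers around the compiled Gotoh aligner.

# encode a sequence as 1-based indices into the scheme's substitution matrix;
# letters outside the matrix map to N (nucleotide) or X (amino acid)
.encodeSeq <- function(x, scheme) {
  letters <- rownames(scheme@submat)
  v <- strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]
  i <- match(v, letters)
  if (anyNA(i)) {
    fallback <- if (scheme@alphabet == "nucleotide") "N" else "X"
    i[is.na(i)] <- match(fallback, letters)
  }
  i
}

.alignEncoded <- function(qi, si, scheme, global) {
  .alignPairC(qi, si, scheme@submat, scheme@gapOpen, scheme@gapExtend, global)
}

#' Optimal local alignment with significance statistics
#'
#' Smith-Waterman local alignment under an affine-gap [ScoringScheme-class],
#' the stand-in for a BLAST search against a small reference panel. The raw
#' score is converted to a bit score and E-value with the scheme's ungapped
#' Karlin-Altschul parameters; by default the search space is
#' `nchar(query) * nchar(subject)` but panel searches supply their own `m`
#' and `n`.
#'
#' @param query,subject Sequences (character or `XString`) over the scheme's
#'   alphabet.
#' @param scheme A [ScoringScheme-class]; defaults to the nucleotide scheme.
#' @param m,n Search-space lengths for the E-value; default to the sequence
#'   lengths.
#' @return A list of class `"alignment_result"` with elements `score`
#'   (raw), `bits`, `evalue`, `identity` (matches / alignment columns,
#'   terminal gaps excluded by construction for local alignments), `matches`,
#'   `columns`, and 0-based half-open spans `queryRange` and `subjectRange`.
#' @examples
#' localAlign("ACGTACGT", "ACGTACGT")$score
#' @export
localAlign <- function(query, subject, scheme = scoringScheme(),
                       m = NULL, n = NULL) {
  q <- as.character(query); s <- as.character(subject)
  if (nchar(q) == 0 || nchar(s) == 0)
    stop("sequences must be non-empty")
  r <- .alignEncoded(.encodeSeq(q, scheme), .encodeSeq(s, scheme),
                     scheme, global = FALSE)
  if (is.null(m)) m <- nchar(q)
  if (is.null(n)) n <- nchar(s)
  out <- list(
    score = r$score,
    bits = bitScore(r$score, scheme),
    evalue = eValue(r$score, m, n, scheme),
    identity = if (r$columns > 0) r$matches / r$columns else 0,
    matches = r$matches, columns = r$columns,
    queryRange = if (is.na(r$qstart)) c(NA_integer_, NA_integer_)
                 else c(r$qstart - 1L, r$qend),
    subjectRange = if (is.na(r$sstart)) c(NA_integer_, NA_integer_)
                   else c(r$sstart - 1L, r$send))
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "local alignment: raw %g, %.1f bits, E = %.3g, identity %.3f (%d/%d)\n",
    x$score, x$bits, x$evalue, x$identity, x$matches, x$columns))
  invisible(x)
}

#' Pairwise identity under global alignment, terminal gaps excluded
#'
#' The identity notion behind the fixed clustering thresholds: a full global
#' (Needleman-Wunsch, affine-gap) alignment is computed and identity is the
#' number of matching columns divided by the number of alignment columns
#' between the first and last aligned residue pair -- terminal-gap columns
#' are excluded from the denominator, internal gap columns count as
#' mismatches. Two sequences whose optimal alignment pairs no residues have
#' identity 0.
#'
#' @param a,b Nucleotide sequences (character or `XString`).
#' @param scheme A nucleotide [ScoringScheme-class].
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")  # 0.75
#' @export
pairwiseIdentity <- function(a, b, scheme = scoringScheme()) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  r <- .alignEncoded(.encodeSeq(a, scheme), .encodeSeq(b, scheme),
                     scheme, global = TRUE)
  if (r$columns > 0) r$matches / r$columns else 0
}

#' Pairwise identity matrix for a set of sequences
#'
#' Symmetric matrix of [pairwiseIdentity()] values; used by the
#' similarity-consensus resolver within flagged clusters.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param scheme A nucleotide [ScoringScheme-class].
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
identityMatrix <- function(seqs, scheme = scoringScheme()) {
  nm <- names(seqs)
  s <- as.character(seqs)
  n <- length(s)
  enc <- lapply(s, .encodeSeq, scheme = scheme)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- .alignEncoded(enc[[i]], enc[[j]], scheme, global = TRUE)
        m[i, j] <- m[j, i] <- if (r$columns > 0) r$matches / r$columns else 0
      }
    }
  }
  dimnames(m) <- list(nm, nm)
  m
}

# global alignment with aligned column bookkeeping (terminal gaps trimmed),
# for the windowed identity profile; per-column query/subject positions
# (NA = internal gap)
.overlapColumns <- function(a, b, scheme = scoringScheme()) {
  ai <- .encodeSeq(a, scheme); bi <- .encodeSeq(b, scheme)
  r <- .alignEncoded(ai, bi, scheme, global = TRUE)
  both <- !is.na(r$ai) & !is.na(r$bi)
  mt <- logical(length(r$ai))
  mt[both] <- ai[r$ai[both]] == bi[r$bi[both]]
  list(qpos = r$ai, spos = r$bi, match = mt,
       score = r$score, matches = r$matches, columns = r$columns)
}
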