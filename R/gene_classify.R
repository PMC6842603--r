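# Gene classification: assign each nucleotide record to exactly one
# mitochondrial gene by local alignment against per-gene reference panels.
# Ribosomal genes (12S/16S) are compared as nucleotides; protein-coding genes
# as amino acids over the best of the six translated reading frames, since
# amino acids separate the genes more efficiently.

#' Translate a nucleotide sequence in a given frame
#'
#' Translates with a mitochondrial (or standard) genetic code. The frame
#' offset is trimmed from the 5' end, a trailing incomplete codon is dropped,
#' and internal stop codons are rendered as `*` rather than truncating the
#' translation. A frame leaving fewer than 3 bases yields an empty
#' translation with a warning.
#'
#' @param nucl Nucleotide sequence (character or `DNAString`).
#' @param frame 0, 1 or 2 (5' offset). Reverse-strand frames are obtained by
#'   passing `Biostrings::reverseComplement`ed input.
#' @param code Genetic code id: `"1"` (standard), `"2"` (vertebrate
#'   mitochondrial) or `"5"` (invertebrate mitochondrial).
#' @return An `AAString`.
#' @examples
#' as.character(translateFrame("ATGATG", 0, "2"))  # "MM"
#' @export
translateFrame <- function(nucl, frame = 0, code = c("5", "2", "1")) {
  code <- match.arg(as.character(code), c("5", "2", "1"))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  x <- Biostrings::DNAString(as.character(nucl))
  if (length(x) == 0) stop("empty input sequence")
  n <- length(x) - frame
  ncod <- n %/% 3
  if (ncod < 1) {
    warning("frame leaves no complete codon; empty translation")
    return(Biostrings::AAString(""))
  }
  x <- Biostrings::subseq(x, start = frame + 1, width = ncod * 3)
  gc <- Biostrings::getGeneticCode(code)
  if (grepl("[^ACGT]", as.character(x)))
    Biostrings::translate(x, genetic.code = gc, if.fuzzy.codon = "X")
  else
    Biostrings::translate(x, genetic.code = gc)
}

# all six translated frames (3 forward + 3 reverse-complement), dropping
# empty ones
.sixFrames <- function(nucl, code = "5") {
  x <- Biostrings::DNAString(as.character(nucl))
  rc <- Biostrings::reverseComplement(x)
  frames <- list()
  for (f in 0:2) {
    for (s in list(x, rc)) {
      if (length(s) - f >= 3) {
        aa <- suppressWarnings(translateFrame(s, f, code))
        if (length(aa) > 0) frames[[length(frames) + 1]] <- as.character(aa)
      }
    }
  }
  frames
}

#' Classify a record to a mitochondrial gene
#'
#' Emulates a BLAST-based gene classification: the record is aligned locally
#' against every reference panel, a hit is significant when the E-value is
#' strictly below `evalueMax` and the bit score strictly above `bitsMin`,
#' and the record is assigned when significant hits name exactly one gene.
#' Records with significant hits to two or more genes are discarded
#' (`multi-gene`), records with none are discarded (`below-threshold`).
#' Protein-coding panels (`AAStringSet`) are searched with the best of the
#' six translated frames; ribosomal panels (`DNAStringSet`) directly as
#' nucleotides. The E-value search space for a panel is the query length
#' times the total panel length, in the panel's alphabet.
#'
#' @param record Nucleotide sequence (character or `DNAString`).
#' @param refs Named list of reference panels, one per gene: `AAStringSet`
#'   for protein-coding genes, `DNAStringSet` for 12S/16S.
#' @param ntScheme,aaScheme Scoring schemes for the two alphabets; built
#'   with defaults when `NULL`.
#' @param evalueMax,bitsMin Acceptance thresholds (E-value < 1e-10 and
#'   bit score > 70 by default).
#' @param code Genetic code id for translation (default invertebrate
#'   mitochondrial, `"5"`).
#' @return One-row `data.frame`: `gene` (or `"unassigned"`), `rawScore`,
#'   `bitScore`, `eValue`, `identity` of the best hit, and
#'   `discardedReason` (`NA`, `"multi-gene"` or `"below-threshold"`).
#' @export
classifyGene <- function(record, refs, ntScheme = NULL, aaScheme = NULL,
                         evalueMax = 1e-10, bitsMin = 70, code = "5") {
  if (length(refs) == 0) stop("refs must contain at least one gene panel")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("refs must be a named list (one panel per gene)")
  if (is.null(ntScheme)) ntScheme <- scoringScheme("nucleotide")
  if (is.null(aaScheme)) aaScheme <- scoringScheme("amino-acid")
  rec <- as.character(record)
  frames <- NULL

  hits <- lapply(names(refs), function(g) {
    panel <- refs[[g]]
    protein <- is(panel, "AAStringSet") ||
      (is.character(panel) && g %in% PROTEIN_GENES)
    if (protein) {
      if (is.null(frames)) frames <<- .sixFrames(rec, code)
      if (length(frames) == 0)
        return(NULL)
      sch <- aaScheme
      queries <- frames
    } else {
      sch <- ntScheme
      queries <- list(rec)
    }
    penc <- lapply(as.character(panel), .encodeSeq, scheme = sch)
    ntot <- sum(vapply(penc, length, 0L))
    best <- NULL
    for (q in queries) {
      qi <- .encodeSeq(q, sch)
      for (p in penc) {
        r <- .alignEncoded(qi, p, sch, global = FALSE)
        if (is.null(best) || r$score > best$score) {
          best <- r
          best$m <- length(qi)
        }
      }
    }
    data.frame(gene = g, rawScore = best$score,
               bitScore = bitScore(best$score, sch),
               eValue = eValue(best$score, best$m, ntot, sch),
               identity = if (best$columns > 0)
                 best$matches / best$columns else 0,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)

  res <- data.frame(gene = "unassigned", rawScore = NA_real_,
                    bitScore = NA_real_, eValue = NA_real_,
                    identity = NA_real_, discardedReason = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) {
    res$discardedReason <- "below-threshold"
    return(res)
  }
  sig <- hits[hits$eValue < evalueMax & hits$bitScore > bitsMin, ,
              drop = FALSE]
  if (nrow(sig) == 0) {
    top <- hits[which.max(hits$bitScore), ]
    res[c("rawScore", "bitScore", "eValue", "identity")] <-
      top[c("rawScore", "bitScore", "eValue", "identity")]
    res$discardedReason <- "below-threshold"
  } else if (length(unique(sig$gene)) >= 2) {
    top <- sig[which.max(sig$bitScore), ]
    res[c("rawScore", "bitScore", "eValue", "identity")] <-
      top[c("rawScore", "bitScore", "eValue", "identity")]
    res$discardedReason <- "multi-gene"
  } else {
    top <- sig[which.max(sig$bitScore), ]
    res$gene <- top$gene
    res[c("rawScore", "bitScore", "eValue", "identity")] <-
      top[c("rawScore", "bitScore", "eValue", "identity")]
  }
  res
}

#' Classify every record of a database
#'
#' Applies [classifyGene()] to each sequence and appends the per-gene length
#' filter verdict for assigned records.
#'
#' @param seqs Named `DNAStringSet` or character vector (names are
#'   accessions).
#' @param refs Named list of per-gene reference panels.
#' @param ... Passed to [classifyGene()].
#' @return `data.frame` with one row per record: `accession`, `gene`,
#'   `rawScore`, `bitScore`, `eValue`, `identity`, `passLengthFilter`,
#'   `discardedReason`.
#' @export
classifyGenes <- function(seqs, refs, ...) {
  ntScheme <- scoringScheme("nucleotide")
  aaScheme <- scoringScheme("amino-acid")
  s <- as.character(seqs)
  rows <- lapply(seq_along(s), function(i) {
    r <- classifyGene(s[[i]], refs, ntScheme = ntScheme,
                      aaScheme = aaScheme, ...)
    r$accession <- names(s)[i]
    r
  })
  out <- do.call(rbind, rows)
  out$passLengthFilter <- NA
  assigned <- out$gene != "unassigned"
  out$passLengthFilter[assigned] <- mapply(
    lengthFilter, out$gene[assigned], nchar(s)[assigned])
  out$discardedReason[assigned & !out$passLengthFilter] <- "length-out-of-range"
  out[, c("accession", "gene", "rawScore", "bitScore", "eValue", "identity",
          "passLengthFilter", "discardedReason")]
}

#' Per-gene length filter
#'
#' Inclusive length windows per gene (see [GENE_LENGTH_WINDOWS]); sequences
#' outside their gene's window are dropped to avoid spurious clustering of
#' very short fragments.
#'
#' @param gene Assigned gene id (one of [MITO_GENES]).
#' @param seqLength Sequence length in bases.
#' @return `TRUE` if the length is inside the window.
#' @examples
#' lengthFilter("CO1", 100)  # TRUE, bounds inclusive
#' lengthFilter("12S", 199)  # FALSE
#' @export
lengthFilter <- function(gene, seqLength) {
  if (is.na(gene) || gene == "unassigned")
    stop("lengthFilter requires an assigned gene")
  w <- GENE_LENGTH_WINDOWS[[gene]]
  if (is.null(w)) stop(sprintf("unknown gene: %s", gene))
  seqLength >= w[1] & seqLength <= w[2]
}
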