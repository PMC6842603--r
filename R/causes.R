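# Ordered decision tree assigning a likely cause to each resolved mislabel:
# data entry -> lab contaminant -> pseudogene -> host/diet -> bacterial ->
# taxonomic revision -> other. The first matching rule wins; the evidence
# string records what fired.

#' Configuration for the cause decision tree
#'
#' @param contaminantGenera Genus names of common laboratory contaminants
#'   (humans, lab rodents and model organisms, common food species,
#'   mosquitos, pets).
#' @param adjacencyWindow Maximum numeric accession difference treated as
#'   "consecutive or nearly consecutive" (data-entry rule).
#' @param genusEditMax Maximum Levenshtein distance between the labeled and
#'   consensus genus names treated as "very similar" (data-entry rule).
#' @param pseudogeneKeywords Keywords searched (case-insensitively) in the
#'   record definition for the pseudogene rule.
#' @param hostDietKeywords Keywords indicating gut-content or parasite
#'   studies (host/diet rule).
#' @param bacterialPanel Optional `DNAStringSet` of bacterial reference
#'   sequences; the bacterial rule fires when a flagged sequence is closer
#'   to this panel than to its cluster's consensus group.
#' @param synonyms `data.frame` with columns `old`, `current`: local
#'   genus-synonym table standing in for online nomenclature lookups
#'   (taxonomic-revision rule).
#' @param window,step,identityDropThreshold Sliding-window parameters for
#'   the chimera branch of the pseudogene rule (window 60 bp, step 30 bp; a
#'   max-min windowed identity spread above 0.30 indicates a drastic
#'   similarity change along the sequence).
#' @param excludedPhyla Phyla whose clusters are not assessed for causes
#'   (mitochondrial resolution too low; default Porifera and Cnidaria).
#' @return A list of class `"cause_config"`.
#' @export
causeConfig <- function(
    contaminantGenera = c("Homo", "Mus", "Rattus", "Bos", "Sus", "Gallus",
                          "Canis", "Felis", "Danio", "Drosophila", "Aedes",
                          "Culex", "Anopheles", "Oncorhynchus", "Salmo"),
    adjacencyWindow = 2,
    genusEditMax = 2,
    pseudogeneKeywords = c("pseudogene", "numt"),
    hostDietKeywords = c("gut content", "stomach content", "parasite",
                         "diet"),
    bacterialPanel = NULL,
    synonyms = data.frame(old = character(), current = character(),
                          stringsAsFactors = FALSE),
    window = 60, step = 30, identityDropThreshold = 0.30,
    excludedPhyla = c("Porifera", "Cnidaria")) {
  structure(list(contaminantGenera = contaminantGenera,
                 adjacencyWindow = adjacencyWindow,
                 genusEditMax = genusEditMax,
                 pseudogeneKeywords = pseudogeneKeywords,
                 hostDietKeywords = hostDietKeywords,
                 bacterialPanel = bacterialPanel,
                 synonyms = synonyms,
                 window = window, step = step,
                 identityDropThreshold = identityDropThreshold,
                 excludedPhyla = excludedPhyla),
            class = "cause_config")
}

#' Sliding-window identity profile along an alignment
#'
#' Aligns a sequence to a reference with free terminal gaps and reports the
#' identity in windows along the aligned span. A chimeric sequence (for
#' instance a nuclear mitochondrial pseudogene fused with unrelated
#' sequence) shows a drastic drop between window identities, whereas a
#' uniformly diverged sequence is flat.
#'
#' @param seq Query sequence.
#' @param ref Reference sequence (typically the nearest same-cluster member
#'   by overall identity).
#' @param window,step Window width and step in alignment columns.
#' @param scheme Nucleotide [ScoringScheme-class].
#' @return `data.frame` with columns `offset` (0-based alignment column of
#'   the window start) and `identity`. Empty, with a warning, when no
#'   alignable region exists.
#' @export
windowedIdentityProfile <- function(seq, ref, window = 60, step = 30,
                                    scheme = scoringScheme()) {
  cols <- .overlapColumns(as.character(seq), as.character(ref), scheme)
  n <- length(cols$match)
  if (n == 0) {
    warning("no alignable region; empty profile")
    return(data.frame(offset = integer(), identity = numeric()))
  }
  window <- min(window, n)
  starts <- seq(1, max(1, n - window + 1), by = step)
  # make sure the profile covers the full aligned span
  if (starts[length(starts)] + window - 1 < n)
    starts <- c(starts, n - window + 1)
  data.frame(
    offset = as.integer(starts - 1),
    identity = vapply(starts, function(s)
      mean(cols$match[s:(s + window - 1)]), 0))
}

.accessionNumber <- function(acc) {
  m <- regmatches(acc, regexec("^([A-Za-z]+)([0-9]+)$", acc))[[1]]
  if (length(m) < 3) return(list(prefix = NA_character_, num = NA_real_))
  list(prefix = toupper(m[2]), num = as.numeric(m[3]))
}

#' Assign a likely error cause to a resolved mislabeled sequence
#'
#' Applies the ordered decision tree to one flagged record within its
#' cluster context. Rules, in order: (1) *data-entry* -- another cluster
#' member of a different labeled genus has a nearly consecutive accession
#' number (same prefix, numeric difference <= `adjacencyWindow`), or the
#' labeled genus name is within Levenshtein distance `genusEditMax` of the
#' consensus genus; (2) *lab-contaminant* -- the cluster's consensus genus
#' is a known laboratory contaminant; (3) *pseudogene* -- the record
#' definition mentions a pseudogene keyword, or the windowed identity
#' profile against the nearest cluster member has a near-identical region
#' (window identity >= 0.9) yet drops by more than the threshold
#' elsewhere; (4) *host-or-diet* -- the definition mentions gut-content or
#' parasite keywords; (5) *bacterial* -- the sequence is closer to the
#' bacterial panel than to the consensus group; (6) *taxonomic-revision* --
#' the labeled genus maps to the consensus genus in the synonym table;
#' otherwise (7) `"other"`. Records in excluded phyla (Porifera, Cnidaria)
#' return `"not-assessed"`.
#'
#' @param accession Accession of the flagged (resolved mislabeled) record.
#' @param members Accessions of the record's cluster.
#' @param lineages Lineage table covering the members.
#' @param seqs Named sequences covering the members (and used against the
#'   bacterial panel).
#' @param definitions Named character vector: accession -> record
#'   definition/title text.
#' @param config A [causeConfig()] list.
#' @param idmat Optional precomputed identity matrix over `members`.
#' @param scheme Nucleotide [ScoringScheme-class].
#' @return One-row `data.frame`: `accession`, `cause`, `evidence`.
#' @export
classifyCause <- function(accession, members, lineages, seqs, definitions,
                          config = causeConfig(), idmat = NULL,
                          scheme = scoringScheme()) {
  lin <- .lineageRows(lineages, members)
  me <- match(accession, members)
  if (is.na(me)) stop("accession must be one of the cluster members")
  ownGenus <- lin$genus[me]
  ownPhylum <- lin$phylum[me]

  # consensus = plurality genus among the other members
  othersLab <- lin$genus[-me]
  othersLab <- othersLab[!is.na(othersLab) & othersLab != "unranked"]
  tab <- sort(table(othersLab), decreasing = TRUE)
  consensusGenus <- if (length(tab)) names(tab)[1] else NA_character_
  consensusPhylum <- if (!is.na(consensusGenus))
    lin$phylum[match(consensusGenus, lin$genus)] else NA_character_

  res <- function(cause, evidence)
    data.frame(accession = accession, cause = cause, evidence = evidence,
               stringsAsFactors = FALSE)

  if (ownPhylum %in% config$excludedPhyla ||
      (!is.na(consensusPhylum) && consensusPhylum %in% config$excludedPhyla))
    return(res("not-assessed",
               "member of an excluded phylum (low mitochondrial resolution)"))

  # (1) data entry
  mine <- .accessionNumber(accession)
  if (!is.na(mine$num)) {
    for (j in seq_along(members)) {
      if (j == me) next
      g <- lin$genus[j]
      if (is.na(g) || g == "unranked" || g == ownGenus) next
      other <- .accessionNumber(members[j])
      if (!is.na(other$num) && identical(other$prefix, mine$prefix) &&
          abs(other$num - mine$num) <= config$adjacencyWindow) {
        return(res("data-entry",
                   sprintf("accession adjacent to %s (labeled %s)",
                           members[j], g)))
      }
    }
  }
  if (!is.na(consensusGenus) && !is.na(ownGenus) && ownGenus != "unranked" &&
      adist(ownGenus, consensusGenus) <= config$genusEditMax &&
      ownGenus != consensusGenus) {
    return(res("data-entry",
               sprintf("labeled genus '%s' within edit distance %d of consensus '%s'",
                       ownGenus, config$genusEditMax, consensusGenus)))
  }

  # (2) laboratory contaminant
  if (!is.na(consensusGenus) && consensusGenus %in% config$contaminantGenera)
    return(res("lab-contaminant",
               sprintf("consensus genus '%s' is a known contaminant",
                       consensusGenus)))

  # (3) pseudogene: keyword or chimeric identity profile
  def <- definitions[[accession]]
  if (!is.null(def) && !is.na(def) &&
      any(vapply(config$pseudogeneKeywords, grepl, TRUE, x = def,
                 ignore.case = TRUE, fixed = FALSE)))
    return(res("pseudogene", "pseudogene keyword in definition"))
  others <- setdiff(members, accession)
  if (length(others)) {
    if (is.null(idmat)) {
      nearest <- others[1]
      bestId <- -1
      for (o in others) {
        id <- pairwiseIdentity(seqs[[accession]], seqs[[o]], scheme)
        if (id > bestId) { bestId <- id; nearest <- o }
      }
    } else {
      nearest <- others[which.max(idmat[accession, others])]
    }
    prof <- suppressWarnings(windowedIdentityProfile(
      seqs[[accession]], seqs[[nearest]], config$window, config$step,
      scheme))
    if (nrow(prof) > 1) {
      # a chimera pairs near-identical windows with alien ones; a uniformly
      # dissimilar sequence (large spread, no high-identity region) is not
      # pseudogene evidence
      drop <- max(prof$identity) - min(prof$identity)
      if (drop > config$identityDropThreshold && max(prof$identity) >= 0.9)
        return(res("pseudogene",
                   sprintf("windowed identity drop %.2f vs %s", drop,
                           nearest)))
    }
  }

  # (4) host or dietary contamination
  if (!is.null(def) && !is.na(def) &&
      any(vapply(config$hostDietKeywords, grepl, TRUE, x = def,
                 ignore.case = TRUE)))
    return(res("host-or-diet", "gut-content/parasite keyword in definition"))

  # (5) bacterial
  if (!is.null(config$bacterialPanel) && length(config$bacterialPanel) &&
      !is.na(consensusGenus)) {
    bactId <- max(vapply(as.character(config$bacterialPanel), function(b)
      pairwiseIdentity(seqs[[accession]], b, scheme), 0))
    consAccs <- members[lin$genus == consensusGenus &
                          !is.na(lin$genus)]
    consAccs <- setdiff(consAccs, accession)
    consId <- if (length(consAccs)) {
      if (is.null(idmat))
        max(vapply(consAccs, function(o)
          pairwiseIdentity(seqs[[accession]], seqs[[o]], scheme), 0))
      else max(idmat[accession, consAccs])
    } else -1
    if (bactId > consId)
      return(res("bacterial",
                 sprintf("bacterial panel identity %.3f > consensus %.3f",
                         bactId, consId)))
  }

  # (6) taxonomic revision
  syn <- config$synonyms
  if (!is.na(consensusGenus) && !is.na(ownGenus) && nrow(syn) > 0) {
    hit <- syn$current[match(ownGenus, syn$old)]
    if (!is.na(hit) && hit == consensusGenus)
      return(res("taxonomic-revision",
                 sprintf("'%s' is a synonym of '%s'", ownGenus,
                         consensusGenus)))
  }

  res("other", "no rule matched")
}
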