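# Strain-level binning of intragenomic alleles by integral abundance ratios,
# and full-complement consensus classification over best-hit tables.

#' Bin ASVs into strain-level allele groups by integral abundance ratios
#'
#' Within one taxonomic group, searches over candidate genome units g (each
#' ASV abundance divided by 1..copyNumber) for a partition of the ASVs into
#' bins in which every member's abundance/g lies within \code{tol} of an
#' integer copy number >= 1 and, when a copy number is supplied, the bin's
#' copies sum to it. Distinct strains are recovered as separate bins when
#' their abundance scales are separated by more than the tolerance.
#' Among valid partitions the most parsimonious is returned: fewest
#' unbinned ASVs, then fewest bins (so that co-varying alleles are explained
#' jointly rather than as one degenerate all-copies bin per ASV), then
#' smallest total deviation. ASVs that fit no bin are reported unbinned.
#'
#' @param abundances named numeric vector of ASV abundances (names are ASV
#'   identifiers; unnamed vectors are labelled asv1, asv2, ...).
#' @param copyNumber known 16S copy number per genome (e.g. 7 for
#'   \emph{E. coli}), or NULL when unknown.
#' @param tol integral-ratio tolerance (default 0.2).
#' @param maxCopies largest per-allele copy number considered when
#'   \code{copyNumber} is NULL (default 12).
#' @return data.frame with columns asv, abundance, bin (integer or NA),
#'   copies, genomeUnit, deviation.
#' @examples
#' binStrains(c(a1 = 300, a2 = 100, a3 = 100, a4 = 100, a5 = 100),
#'            copyNumber = 7)
#' @export
binStrains <- function(abundances, copyNumber = NULL, tol = 0.2,
                       maxCopies = 12L) {
  if (length(abundances) < 1) stop("need at least one ASV", call. = FALSE)
  if (is.null(names(abundances)))
    names(abundances) <- sprintf("asv%d", seq_along(abundances))
  ab <- abundances
  maxc <- if (is.null(copyNumber)) as.integer(maxCopies) else as.integer(copyNumber)
  # lexicographic cost: (unbinned ASVs, bins, total deviation)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$cost[1] != b$cost[1]) return(a$cost[1] < b$cost[1])
    if (a$cost[2] != b$cost[2]) return(a$cost[2] < b$cost[2])
    a$cost[3] < b$cost[3] - 1e-12
  }

  solve_rec <- function(idx) {
    if (!length(idx)) return(list(bins = list(), cost = c(0, 0, 0)))
    i0 <- idx[which.max(ab[idx])]
    best <- NULL
    # candidate genome units: every member abundance divided by 1..maxc
    cand_g <- unique(signif(as.numeric(outer(ab[idx], seq_len(maxc), "/")), 8))
    for (g in cand_g) {
      if (g <= 0) next
      ratios <- ab[idx] / g
      comp <- idx[abs(ratios - round(ratios)) <= tol & round(ratios) >= 1 &
                    round(ratios) <= maxc]
      if (!(i0 %in% comp)) next
      # refine the genome unit from the provisional copy assignment and
      # re-collect compatible members under the refined unit
      cp <- round(ab[comp] / g)
      g2 <- sum(ab[comp]) / sum(cp)
      ratios2 <- ab[idx] / g2
      comp <- idx[abs(ratios2 - round(ratios2)) <= tol & round(ratios2) >= 1 &
                    round(ratios2) <= maxc]
      if (!length(comp) || !(i0 %in% comp)) next
      cp <- round(ab[comp] / g2)
      if (!is.null(copyNumber) && sum(cp) != copyNumber) {
        comp <- .copy_subset(comp, cp, ab, g2, copyNumber, i0)
        if (is.null(comp)) next
        cp <- round(ab[comp] / g2)
      }
      gfin <- sum(ab[comp]) / sum(cp)
      dev <- abs(ab[comp] / gfin - round(ab[comp] / gfin))
      if (any(dev > tol) || any(round(ab[comp] / gfin) < 1)) next
      sub <- solve_rec(setdiff(idx, comp))
      cand <- list(bins = c(list(list(members = comp,
                                      copies = as.integer(round(ab[comp] / gfin)),
                                      unit = gfin, dev = dev)), sub$bins),
                   cost = sub$cost + c(0, 1, sum(dev)))
      if (better(cand, best)) best <- cand
    }
    # leaving i0 unbinned is the fallback
    sub <- solve_rec(setdiff(idx, i0))
    cand <- list(bins = c(list(list(members = i0, copies = NA_integer_,
                                    unit = NA_real_, dev = NA_real_,
                                    unbinned = TRUE)), sub$bins),
                 cost = sub$cost + c(1, 0, 0))
    if (better(cand, best)) best <- cand
    best
  }

  sol <- solve_rec(seq_along(ab))
  out <- data.frame(asv = names(ab), abundance = as.numeric(ab),
                    bin = NA_integer_, copies = NA_integer_,
                    genomeUnit = NA_real_, deviation = NA_real_,
                    stringsAsFactors = FALSE)
  binno <- 0L
  for (b in sol$bins) {
    if (isTRUE(b$unbinned)) next
    binno <- binno + 1L
    out$bin[b$members] <- binno
    out$copies[b$members] <- b$copies
    out$genomeUnit[b$members] <- b$unit
    out$deviation[b$members] <- b$dev
  }
  rownames(out) <- NULL
  out
}

# choose the subset of a provisional bin whose copies sum to the known copy
# number (must contain the anchor ASV), minimizing total deviation
.copy_subset <- function(comp, cp, ab, g, copyNumber, anchor) {
  if (sum(cp) < copyNumber) return(NULL)
  if (length(comp) > 16L) return(NULL)
  dev <- abs(ab[comp] / g - cp)
  best <- NULL; bestdev <- Inf
  nn <- length(comp)
  for (m in seq_len(2^nn) - 1L) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(nn) - 1L)))
    if (!any(sel)) next
    if (!(anchor %in% comp[sel])) next
    if (sum(cp[sel]) != copyNumber) next
    d <- sum(dev[sel])
    if (d < bestdev) { bestdev <- d; best <- comp[sel] }
  }
  best
}

#' Read a best-hit table from TSV
#'
#' Expected columns: \code{asv}, \code{accession}, plus any metadata columns
#' (e.g. \code{serotype}, \code{strain}); empty strings are treated as
#' missing metadata.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readHitTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("asv", "accession") %in% names(df)))
    stop("hit table needs 'asv' and 'accession' columns", call. = FALSE)
  df
}

#' Full-complement consensus classification over best-hit sets
#'
#' Tabulates how many ASVs each accession is a best hit for; the accessions
#' with the maximal occurrence count form the consensus set. The metadata
#' field of interest is read across that set, ignoring accessions where it
#' is missing: a unanimous value classifies the strain; conflicting values
#' yield \code{"ambiguous"}; all-missing yields \code{"unclassified"}.
#'
#' @param hits data.frame with columns \code{asv}, \code{accession} and the
#'   metadata column named by \code{metadataField} (missing entries NA or "").
#' @param metadataField metadata column to classify by (e.g. "serotype").
#' @return list with \code{classification}, \code{supportingAccessions}
#'   (size of the consensus set), \code{maxOccurrence} (ASVs hit),
#'   \code{values} (table of non-missing metadata values in the set).
#' @export
consensusClassify <- function(hits, metadataField) {
  if (is.null(hits) || nrow(hits) == 0)
    stop("empty hit table", call. = FALSE)
  if (!metadataField %in% names(hits))
    stop("no such metadata column: ", metadataField, call. = FALSE)
  # occurrences: in how many ASV best-hit sets does each accession appear
  occ <- table(unique(hits[, c("asv", "accession")])$accession)
  top <- names(occ)[occ == max(occ)]
  meta <- hits[[metadataField]][match(top, hits$accession)]
  meta <- meta[!is.na(meta) & nzchar(meta)]
  classification <- if (!length(meta)) "unclassified"
    else if (length(unique(meta)) == 1L) unique(meta)
    else "ambiguous"
  list(classification = classification,
       supportingAccessions = length(top),
       maxOccurrence = as.integer(max(occ)),
       values = table(meta))
}

#' Illumina-recommended V3V4 primer pair
#' @return a \code{\link{PrimerSpec-class}} (341F/805R).
#' @export
v3v4Primers <- function() primerSpec("CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC")

#' JGI-recommended V4V5 primer pair
#' @return a \code{\link{PrimerSpec-class}} (515F/926R).
#' @export
v4v5Primers <- function() primerSpec("GTGYCAGCMGCCGCGGTAA", "CCGYCAATTYMTTTRAGTTT")

#' Extract the sub-region between a primer pair from a full-length sequence
#'
#' Returns the region strictly between the forward primer match and the
#' reverse-complemented reverse primer match, or \code{NULL} when either is
#' absent. When the forward primer matches more than once the first match is
#' used and a warning is raised.
#'
#' @param sequence full-length nucleotide string.
#' @param primers a \code{\link{PrimerSpec-class}} (e.g.
#'   \code{\link{v3v4Primers}()}); only exact IUPAC matches are considered.
#' @return the sub-region string, or \code{NULL}.
#' @export
extractSubregion <- function(sequence, primers) {
  stopifnot(is(primers, "PrimerSpec"))
  subj <- Biostrings::DNAString(sequence)
  mf <- Biostrings::matchPattern(primers@forward, subj, fixed = FALSE)
  if (length(mf) == 0) return(NULL)
  if (length(mf) > 1)
    warning("multiple forward primer matches; using the first")
  mr <- Biostrings::matchPattern(C_revcomp(primers@reverse), subj, fixed = FALSE)
  mr <- mr[Biostrings::start(mr) > Biostrings::end(mf)[1]]
  if (length(mr) == 0) return(NULL)
  substr(sequence, Biostrings::end(mf)[1] + 1L, Biostrings::start(mr)[1] - 1L)
}
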