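# De novo two-parent (bimera) chimera detection with the
# parent-overabundance safeguard needed for multi-copy genes: intragenomic
# 16S alleles occur at small integral abundance ratios to one another, so a
# minimum parent/candidate abundance fold below which no sequence can be
# called a chimera protects genuine minor alleles from being explained away
# as mosaics of their more abundant same-genome siblings.

# longest common prefix / suffix of two strings, in bases
.lcp <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (!length(neq)) n else neq[1] - 1L
}
.lcs <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (!length(neq)) n else neq[1] - 1L
}

# Error-free candidate prefix/suffix length with respect to one parent.
# A mosaic's left segment is anchored at position 1 of both candidate and
# parent, so the plain longest common prefix captures it (likewise the
# suffix at the right end); the banded alignment extents are kept as a
# fallback for segments sitting at small shifted offsets, since a global
# alignment of a half-matching pair may trade gaps inside the clean segment
# for score in the mismatch-rich half.
.chimera_extents <- function(candidate, parent, maxShift, match, mismatch, gap) {
  L <- nchar(candidate)
  if (candidate == parent)
    return(list(exact = TRUE, prefix = L, suffix = L))
  prefix <- .lcp(candidate, parent)
  suffix <- .lcs(candidate, parent)
  al <- alignBanded(candidate, parent, band = maxShift, match = match,
                    mismatch = mismatch, gap = gap)
  if (!is.null(al)) {
    ac <- strsplit(al$alignment[1], "", fixed = TRUE)[[1]]
    ap <- strsplit(al$alignment[2], "", fixed = TRUE)[[1]]
    disc <- ac == "-" | ap == "-" | ac != ap
    cpos <- cumsum(ac != "-")
    if (!any(disc)) return(list(exact = TRUE, prefix = L, suffix = L))
    first <- which(disc)[1]; last <- which(disc)[length(which(disc))]
    prefix <- max(prefix, if (first == 1) 0L else cpos[first - 1L])
    suffix <- max(suffix, L - cpos[last])
  } else if (prefix == 0L && suffix == 0L) {
    return(NULL)
  }
  list(exact = FALSE, prefix = prefix, suffix = suffix)
}

#' Test one sequence for being a two-parent chimera (bimera)
#'
#' The candidate is a bimera iff some ordered pair of sufficiently abundant
#' pool members reconstructs it exactly as a one-crossover mosaic: a left
#' segment matching parent A perfectly and the remaining right segment
#' matching parent B perfectly (under banded alignment with shifts up to
#' \code{maxShift} columns), while neither parent alone matches it exactly.
#' Only pool members at least \code{minFold} times more abundant than the
#' candidate qualify as parents.
#'
#' @param candidate candidate ASV sequence.
#' @param candidateAbundance its abundance.
#' @param pool data.frame with columns \code{sequence} and \code{abundance}
#'   (the other ASVs of the sample).
#' @param minFold minimum parent/candidate abundance fold (default 3.5, the
#'   value appropriate for full-length 16S data where intragenomic alleles
#'   occur at up to ~3x copy-number ratios).
#' @param maxShift alignment band half-width at the crossover search
#'   (default 16).
#' @param match,mismatch,gap alignment scoring.
#' @return list with \code{isBimera}, and when \code{TRUE},
#'   \code{parentA}, \code{parentB} (sequences) and \code{crossover}
#'   (1-based candidate position of the first base that can derive from
#'   parent B).
#' @export
isBimera <- function(candidate, candidateAbundance, pool, minFold = 3.5,
                     maxShift = 16L, match = 5L, mismatch = -4L, gap = -8L) {
  if (minFold <= 0) stop("minFold must be positive", call. = FALSE)
  no <- list(isBimera = FALSE, parentA = NULL, parentB = NULL, crossover = NULL)
  if (is.null(pool) || nrow(pool) == 0) return(no)
  if (candidate %in% pool$sequence) return(no)
  ok <- pool$abundance >= minFold * candidateAbundance &
    pool$sequence != candidate
  parents <- pool[ok, , drop = FALSE]
  if (nrow(parents) == 0) return(no)
  L <- nchar(candidate)
  ext <- lapply(parents$sequence, .chimera_extents, candidate = candidate,
                maxShift = maxShift, match = match, mismatch = mismatch,
                gap = gap)
  keep <- !vapply(ext, is.null, logical(1))
  parents <- parents[keep, , drop = FALSE]; ext <- ext[keep]
  if (!length(ext)) return(no)
  if (any(vapply(ext, `[[`, logical(1), "exact"))) return(no)
  pre <- vapply(ext, `[[`, numeric(1), "prefix")
  suf <- vapply(ext, `[[`, numeric(1), "suffix")
  for (a in order(-pre)) {
    if (pre[a] < 1) break
    for (b in order(-suf)) {
      if (b == a) next
      if (suf[b] < 1) break
      if (pre[a] + suf[b] >= L) {
        return(list(isBimera = TRUE,
                    parentA = parents$sequence[a],
                    parentB = parents$sequence[b],
                    crossover = as.integer(max(2L, L - suf[b] + 1L))))
      }
    }
  }
  no
}

#' Remove bimeras from an ASV table
#'
#' Each ASV is judged per sample against that sample's more abundant ASVs
#' (the candidate's parents must exceed \code{minFold} times its abundance
#' in that sample). An ASV is removed table-wide iff it is flagged in a
#' strict majority of the samples in which it occurs.
#'
#' @param table an \code{\link{AsvTable-class}}.
#' @param minFold minimum parent overabundance (default 3.5).
#' @param maxShift crossover-search band half-width (default 16).
#' @return list with \code{table} (cleaned \code{\link{AsvTable-class}}) and
#'   \code{flagged} (data.frame: sequence, samplesPresent, samplesFlagged,
#'   removed, parentA, parentB, crossover from the first flagging sample).
#' @export
removeBimeras <- function(table, minFold = 3.5, maxShift = 16L) {
  stopifnot(is(table, "AsvTable"))
  tb <- table@table
  seqs <- colnames(tb)
  nflag <- integer(ncol(tb)); npres <- integer(ncol(tb))
  pA <- character(ncol(tb)); pB <- character(ncol(tb)); xo <- rep(NA_integer_, ncol(tb))
  for (s in seq_len(nrow(tb))) {
    abund <- tb[s, ]
    present <- which(abund > 0)
    npres[present] <- npres[present] + 1L
    for (j in present) {
      pool <- data.frame(sequence = seqs[present[present != j]],
                         abundance = abund[present[present != j]],
                         stringsAsFactors = FALSE)
      v <- isBimera(seqs[j], abund[j], pool, minFold = minFold,
                    maxShift = maxShift)
      if (v$isBimera) {
        nflag[j] <- nflag[j] + 1L
        if (!nzchar(pA[j])) { pA[j] <- v$parentA; pB[j] <- v$parentB; xo[j] <- v$crossover }
      }
    }
  }
  removed <- nflag > npres / 2
  flagged <- data.frame(sequence = seqs, samplesPresent = npres,
                        samplesFlagged = nflag, removed = removed,
                        parentA = ifelse(nzchar(pA), pA, NA_character_),
                        parentB = ifelse(nzchar(pB), pB, NA_character_),
                        crossover = xo, stringsAsFactors = FALSE)
  flagged <- flagged[flagged$samplesFlagged > 0, , drop = FALSE]
  rownames(flagged) <- NULL
  list(table = new("AsvTable", table = tb[, !removed, drop = FALSE]),
       flagged = flagged)
}
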