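# Mock-community evaluation analytics: genomic-abundance normalization,
# integral allele-ratio accuracy calls, raw-read error profiling,
# rarefaction and replicate concordance.

#' Genomic abundance of a strain from its ASV abundances
#'
#' The abundances of all ASVs assigned to a strain are summed and divided by
#' the strain's 16S rRNA gene copy number, converting allele-level counts to
#' a genome-level abundance.
#'
#' @param asvAbundances numeric vector of ASV abundances assigned to one
#'   strain.
#' @param copyNumber the strain's 16S gene copy number (>= 1).
#' @return genome abundance (reads per genome unit).
#' @examples
#' genomicAbundance(c(300, 100, 100, 100, 100), 7)  # 100
#' @export
genomicAbundance <- function(asvAbundances, copyNumber) {
  if (length(asvAbundances) < 1) stop("need at least one ASV", call. = FALSE)
  if (copyNumber < 1) stop("copyNumber must be >= 1", call. = FALSE)
  sum(asvAbundances) / copyNumber
}

#' ASV abundances normalized to the genomic abundance of their strain
#'
#' For genuine intragenomic alleles these ratios fall on integers equal to
#' the allele's within-genome copy number.
#'
#' @param asvAbundances numeric vector of ASV abundances.
#' @param genomeAbundance the strain's genomic abundance (> 0).
#' @return per-ASV ratios.
#' @export
normalizedRatios <- function(asvAbundances, genomeAbundance) {
  if (genomeAbundance <= 0) stop("genomeAbundance must be positive", call. = FALSE)
  asvAbundances / genomeAbundance
}

#' Integral-ratio accuracy check
#'
#' An ASV:genome ratio passes when it lies within \code{tol} of an integer
#' number of copies per genome, at least one.
#'
#' @param ratio positive ratio(s) of ASV abundance to genomic abundance.
#' @param tol allowed deviation from the nearest integer (default 0.2).
#' @return data.frame with \code{nearest}, \code{deviation}, \code{pass}.
#' @examples
#' integralRatioCheck(c(1.15, 1.45, 0.1))
#' @export
integralRatioCheck <- function(ratio, tol = 0.2) {
  nearest <- round(ratio)
  deviation <- abs(ratio - nearest)
  data.frame(ratio = ratio, nearest = as.integer(nearest),
             deviation = deviation, pass = deviation <= tol & nearest >= 1)
}

#' Multifaceted per-ASV accuracy assessment
#'
#' An ASV is called \code{exact} when its sequence exactly matches a
#' reference allele of its assigned strain; otherwise \code{supported} when
#' its copy-per-genome ratio is integral (within \code{tol}) and its strain
#' bin holds at least two alleles; otherwise \code{unsupported}.
#'
#' @param asv data.frame with columns \code{sequence}, \code{abundance} and
#'   \code{strain} (NA for unassigned ASVs).
#' @param references data.frame with columns \code{strain} and
#'   \code{sequence} (known alleles; may be incomplete).
#' @param copyNumbers named integer vector: strain -> 16S copy number.
#' @param tol integral-ratio tolerance (default 0.2).
#' @return list with \code{verdicts} (data.frame: sequence, strain, ratio,
#'   verdict, reason) and \code{summary} (named counts per class).
#' @export
assessAccuracy <- function(asv, references, copyNumbers, tol = 0.2) {
  stopifnot(all(c("sequence", "abundance", "strain") %in% names(asv)))
  verdict <- character(nrow(asv)); reason <- character(nrow(asv))
  ratio <- rep(NA_real_, nrow(asv))
  for (st in unique(asv$strain[!is.na(asv$strain)])) {
    ix <- which(asv$strain == st)
    cn <- copyNumbers[[st]]
    if (is.null(cn) || is.na(cn)) {
      verdict[ix] <- "unsupported"; reason[ix] <- "unknown copy number"
      next
    }
    ga <- genomicAbundance(asv$abundance[ix], cn)
    ratio[ix] <- normalizedRatios(asv$abundance[ix], ga)
    refs <- references$sequence[references$strain == st]
    chk <- integralRatioCheck(ratio[ix], tol)
    for (t in seq_along(ix)) {
      i <- ix[t]
      if (asv$sequence[i] %in% refs) {
        verdict[i] <- "exact"; reason[i] <- "matches reference allele"
      } else if (chk$pass[t] && length(ix) >= 2) {
        verdict[i] <- "supported"
        reason[i] <- sprintf("integral ratio %.2f (%d copies)",
                             ratio[i], chk$nearest[t])
      } else {
        verdict[i] <- "unsupported"
        reason[i] <- if (length(ix) < 2) "single-allele bin, no reference match"
                     else sprintf("non-integral ratio %.2f", ratio[i])
      }
    }
  }
  una <- is.na(asv$strain)
  verdict[una] <- "unsupported"; reason[una] <- "not assigned to a strain"
  verdicts <- data.frame(sequence = asv$sequence, strain = asv$strain,
                         ratio = ratio, verdict = verdict, reason = reason,
                         stringsAsFactors = FALSE)
  summ <- c(exact = sum(verdict == "exact"),
            supported = sum(verdict == "supported"),
            unsupported = sum(verdict == "unsupported"))
  list(verdicts = verdicts, summary = summ)
}

#' Profile raw-read errors against known true sequences
#'
#' Each read is aligned (banded) to the truth it best matches by alignment
#' score (candidates pre-screened by kmer distance; ties broken by input
#' order of the truths), and every difference is recorded by type
#' (substitution, insertion, deletion), 1-based position in the read, and
#' associated quality score. Insertions are attributed the inserted base's
#' quality; deletions carry no quality. Reads matching no truth within the
#' band are excluded and counted.
#'
#' @param reads a primer-trimmed, oriented \code{\link{QualReadSet-class}}.
#' @param truth character vector of true sequences.
#' @param band alignment band half-width (default 32).
#' @param kdistCutoff kmer screen for candidate truths (default 0.42).
#' @param kmerSize kmer size (default 8).
#' @param match,mismatch,gap alignment scoring.
#' @param exclude read ids to exclude up front (e.g. known chimeras).
#' @return an \code{\link{ErrorProfile-class}}.
#' @export
profileErrors <- function(reads, truth, band = 32L, kdistCutoff = 0.42,
                          kmerSize = 8L, match = 5L, mismatch = -4L,
                          gap = -8L, exclude = NULL) {
  stopifnot(is(reads, "QualReadSet"))
  if (!length(truth)) stop("truth must be non-empty", call. = FALSE)
  keep <- !(reads@id %in% exclude)
  reads <- reads[which(keep)]
  n <- length(reads)
  maxlen <- max(c(nchar(reads@sequence), nchar(truth))) + 8L
  sub_tab <- matrix(0, nrow = maxlen, ncol = 94)
  ins_tab <- matrix(0, nrow = maxlen, ncol = 94)
  del_tab <- numeric(maxlen)
  pos_tot <- numeric(maxlen)
  total_bases <- 0; excluded <- 0L
  ka <- C_kmer_arrays(c(truth, reads@sequence), as.integer(kmerSize))
  nt <- length(truth)
  for (r in seq_len(n)) {
    km <- C_kmer_compare_many(ka$ordered[[nt + r]], ka$sorted[[nt + r]],
                              ka$ordered[seq_len(nt)], ka$sorted[seq_len(nt)])
    cand <- which(km[, 1] <= kdistCutoff)
    if (!length(cand)) { excluded <- excluded + 1L; next }
    sc <- C_score_batch(reads@sequence[r], truth[cand], as.integer(band),
                        as.integer(match), as.integer(mismatch),
                        as.integer(gap))
    if (all(is.na(sc))) { excluded <- excluded + 1L; next }
    bi <- cand[which.max(sc)]  # which.max skips NA; ties -> first in input order
    al <- C_align_batch(truth[bi], reads@sequence[r], FALSE,
                        as.integer(band), as.integer(match),
                        as.integer(mismatch), as.integer(gap))[[1]]
    at <- strsplit(al[1], "", fixed = TRUE)[[1]]
    ao <- strsplit(al[2], "", fixed = TRUE)[[1]]
    q <- reads@quality[[r]]
    rpos <- cumsum(ao != "-")          # read position per column
    rpos_at <- pmax(pmin(rpos, length(q)), 1L)
    both <- at != "-" & ao != "-"
    total_bases <- total_bases + sum(at != "-")
    pos_tot[rpos[both]] <- pos_tot[rpos[both]] + 1
    mm <- both & at != ao
    if (any(mm)) {
      idx <- cbind(rpos[mm], q[rpos[mm]] + 1L)
      for (t in seq_len(nrow(idx))) sub_tab[idx[t, 1], idx[t, 2]] <-
          sub_tab[idx[t, 1], idx[t, 2]] + 1
    }
    ins <- at == "-"
    if (any(ins)) {
      idx <- cbind(rpos[ins], q[rpos[ins]] + 1L)
      for (t in seq_len(nrow(idx))) ins_tab[idx[t, 1], idx[t, 2]] <-
          ins_tab[idx[t, 1], idx[t, 2]] + 1
    }
    del <- ao == "-"
    if (any(del)) {
      # a deletion has no read base: index it at the next read position
      dp <- pmin(rpos[del] + 1L, maxlen)
      for (t in dp) del_tab[t] <- del_tab[t] + 1
    }
  }
  tl <- list()
  nz <- which(sub_tab > 0, arr.ind = TRUE)
  if (nrow(nz)) tl$sub <- data.frame(type = "substitution", position = nz[, 1],
                                     quality = nz[, 2] - 1L,
                                     count = sub_tab[nz])
  nz <- which(ins_tab > 0, arr.ind = TRUE)
  if (nrow(nz)) tl$ins <- data.frame(type = "insertion", position = nz[, 1],
                                     quality = nz[, 2] - 1L,
                                     count = ins_tab[nz])
  nz <- which(del_tab > 0)
  if (length(nz)) tl$del <- data.frame(type = "deletion", position = nz,
                                       quality = NA_integer_,
                                       count = del_tab[nz])
  tallies <- if (length(tl)) do.call(rbind, tl) else
    data.frame(type = character(), position = integer(),
               quality = integer(), count = numeric())
  rownames(tallies) <- NULL
  new("ErrorProfile", tallies = tallies, totalBases = total_bases,
      positionTotals = pos_tot, excluded = excluded,
      nreads = as.integer(n - excluded))
}

#' Aggregate per-type error rates of a profile
#'
#' Tallies divided by the total aligned reference bases.
#'
#' @param profile an \code{\link{ErrorProfile-class}}.
#' @return named numeric: substitution, insertion, deletion, total.
#' @export
aggregateErrorRates <- function(profile) {
  stopifnot(is(profile, "ErrorProfile"))
  tl <- profile@tallies
  tot <- max(profile@totalBases, 1)
  r <- vapply(c("substitution", "insertion", "deletion"), function(ty)
    sum(tl$count[tl$type == ty]) / tot, numeric(1))
  c(r, total = sum(r))
}

#' Rarefy a count vector to fixed depth
#'
#' Uniform subsampling of reads without replacement, reproducible under a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param counts named non-negative integer vector.
#' @param depth target total (must not exceed \code{sum(counts)}).
#' @param seed integer seed.
#' @return integer vector like \code{counts} summing to \code{depth}.
#' @export
rarefyCounts <- function(counts, depth, seed = 1L) {
  if (sum(counts) < depth)
    stop("depth exceeds the total count", call. = FALSE)
  if (sum(counts) == depth) return(counts)
  units <- rep(seq_along(counts), counts)
  take <- .with_seed(seed, sample(units, depth))
  out <- tabulate(take, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Concordance between two technical-replicate ASV tables
#'
#' An observation is a (sample, ASV) pair with positive abundance. Reports
#' the counts of shared and replicate-unique observations over the shared
#' samples, and the Pearson correlation of abundances over the union of
#' observations (absences as 0).
#'
#' @param tableA,tableB \code{\link{AsvTable-class}} objects sharing sample
#'   identifiers.
#' @return list with \code{shared}, \code{aOnly}, \code{bOnly},
#'   \code{pearson}.
#' @export
replicateConcordance <- function(tableA, tableB) {
  stopifnot(is(tableA, "AsvTable"), is(tableB, "AsvTable"))
  samples <- intersect(sampleNames(tableA), sampleNames(tableB))
  if (!length(samples)) stop("the tables share no samples", call. = FALSE)
  ta <- tableA@table[samples, , drop = FALSE]
  tb <- tableB@table[samples, , drop = FALSE]
  allseq <- union(colnames(ta), colnames(tb))
  fa <- matrix(0, length(samples), length(allseq),
               dimnames = list(samples, allseq))
  fb <- fa
  fa[, colnames(ta)] <- ta
  fb[, colnames(tb)] <- tb
  inA <- fa > 0; inB <- fb > 0
  both <- inA | inB
  list(shared = sum(inA & inB), aOnly = sum(inA & !inB),
       bOnly = sum(!inA & inB),
       pearson = if (sum(both) > 1) stats::cor(fa[both], fb[both]) else NA_real_)
}
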