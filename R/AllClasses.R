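# S4 classes for the long-read denoising workflow.

#' QualReadSet: amplicon reads with per-base qualities
#'
#' A set of (possibly oriented) amplicon reads. Sequences are plain
#' ACGTN strings; qualities are integer Phred scores in [0, 93], one per base.
#' Orientation is \code{"forward"}, \code{"rc"} (the read was
#' reverse-complemented to reach forward orientation) or \code{"unknown"}.
#'
#' @slot id character, read identifiers.
#' @slot sequence character, nucleotide strings over A/C/G/T/N.
#' @slot quality list of integer vectors, one per read, each in [0, 93].
#' @slot orientation character, per-read orientation.
#' @exportClass QualReadSet
setClass("QualReadSet",
  representation(id = "character", sequence = "character",
                 quality = "list", orientation = "character"),
  prototype(id = character(), sequence = character(),
            quality = list(), orientation = character()))

setValidity("QualReadSet", function(object) {
  n <- length(object@sequence)
  if (length(object@id) != n || length(object@quality) != n ||
      length(object@orientation) != n)
    return("id, sequence, quality and orientation must have equal length")
  if (n > 0) {
    if (!all(nchar(object@sequence) == lengths(object@quality)))
      return("sequence length must equal the number of quality scores")
    qr <- range(unlist(object@quality, use.names = FALSE), na.rm = TRUE)
    if (length(unlist(object@quality)) && (qr[1] < 0 || qr[2] > 93))
      return("qualities must lie in [0, 93]")
    if (!all(object@orientation %in% c("forward", "rc", "unknown")))
      return("orientation must be 'forward', 'rc' or 'unknown'")
  }
  TRUE
})

#' PrimerSpec: a degenerate primer pair
#'
#' @slot forward,reverse IUPAC primer strings (reverse given in its own
#'   5'->3' orientation, as usual for PCR primers).
#' @slot maxMismatch maximum mismatches tolerated per primer.
#' @slot searchWindow number of bases from each read end that are searched.
#' @exportClass PrimerSpec
setClass("PrimerSpec",
  representation(forward = "character", reverse = "character",
                 maxMismatch = "integer", searchWindow = "integer"))

setValidity("PrimerSpec", function(object) {
  for (p in c(object@forward, object@reverse)) {
    if (!nzchar(p)) return("primers must be non-empty")
    if (!.is_iupac(p)) return(sprintf("invalid IUPAC characters in primer '%s'", p))
  }
  if (object@maxMismatch < 0L) return("maxMismatch must be >= 0")
  if (object@searchWindow < 1L) return("searchWindow must be positive")
  TRUE
})

#' FilterParams: read filtering thresholds
#'
#' @slot minLen,maxLen length bounds (nt) on the primer-trimmed read.
#' @slot maxEE maximum expected errors, sum of 10^(-q/10) over the read.
#' @slot maxN maximum number of N bases tolerated.
#' @exportClass FilterParams
setClass("FilterParams",
  representation(minLen = "integer", maxLen = "integer",
                 maxEE = "numeric", maxN = "integer"))

setValidity("FilterParams", function(object) {
  if (object@minLen < 1L || object@maxLen < 1L) return("length bounds must be positive")
  if (object@minLen > object@maxLen) return("minLen must be <= maxLen")
  if (object@maxEE <= 0) return("maxEE must be positive")
  if (object@maxN < 0L) return("maxN must be >= 0")
  TRUE
})

#' TransitionCounts: observed (true base, read base, quality) tallies
#'
#' A 4 x 4 x 94 array of non-negative counts indexed by true nucleotide,
#' observed nucleotide and quality score 0-93. Indel events are tallied
#' separately (they carry no substitution cell) together with the number of
#' aligned bases, so that a quality-independent indel rate can be estimated.
#'
#' @slot counts numeric 4 x 4 x 94 array (A,C,G,T x A,C,G,T x q = 0..93).
#' @slot indels numeric, total insertion + deletion events observed.
#' @slot alignedBases numeric, total aligned (non-gap) bases observed.
#' @exportClass TransitionCounts
setClass("TransitionCounts",
  representation(counts = "array", indels = "numeric", alignedBases = "numeric"))

setValidity("TransitionCounts", function(object) {
  if (!identical(dim(object@counts), c(4L, 4L, 94L)))
    return("counts must be a 4 x 4 x 94 array")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (object@indels < 0 || object@alignedBases < 0)
    return("indel and aligned-base totals must be non-negative")
  TRUE
})

#' ErrorModel: quality-conditioned transition rates
#'
#' Rates p(observed | true, q) for true/observed in A,C,G,T and quality
#' q = 0..93. Rows of each quality slice sum to one; the twelve error
#' transitions are non-increasing in q over 0..92, while the q = 93 entry is
#' estimated independently of the smooth fit (CCS instruments emit a large
#' point mass at the maximum score, whose error rate does not extrapolate
#' from the rest of the distribution). A single quality-independent indel
#' rate accompanies the substitution matrix.
#'
#' @slot rates numeric 4 x 4 x 94 array of transition rates in (0, 1).
#' @slot indelRate numeric scalar, per-aligned-base indel rate.
#' @slot totals numeric 4 x 94 matrix of training observations per
#'   (true base, quality); used for aggregate-rate summaries and plotting.
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(rates = "array", indelRate = "numeric", totals = "matrix"))

setValidity("ErrorModel", function(object) {
  if (!identical(dim(object@rates), c(4L, 4L, 94L)))
    return("rates must be a 4 x 4 x 94 array")
  if (any(object@rates <= 0) || any(object@rates >= 1))
    return("rates must lie strictly in (0, 1)")
  sums <- apply(object@rates, c(1, 3), sum)
  if (any(abs(sums - 1) > 1e-8))
    return("rates must sum to 1 over observed bases for every (true, q)")
  if (object@indelRate <= 0 || object@indelRate >= 1)
    return("indelRate must lie in (0, 1)")
  TRUE
})

#' UniqueSequenceSet: dereplicated reads
#'
#' One entry per distinct read sequence, with multiplicity, the position-wise
#' mean quality profile, and the map from input reads to unique index.
#'
#' @slot sequence character, distinct sequences, ordered by decreasing
#'   abundance (ties broken lexicographically).
#' @slot abundance integer multiplicities.
#' @slot qualityProfile list of numeric vectors: per-position mean quality.
#' @slot map integer, input read -> unique index.
#' @slot readQuality list of integer vectors: the per-read qualities of the
#'   input reads (kept for error-model training).
#' @exportClass UniqueSequenceSet
setClass("UniqueSequenceSet",
  representation(sequence = "character", abundance = "integer",
                 qualityProfile = "list", map = "integer",
                 readQuality = "list"))

setValidity("UniqueSequenceSet", function(object) {
  n <- length(object@sequence)
  if (length(object@abundance) != n || length(object@qualityProfile) != n)
    return("sequence, abundance and qualityProfile must have equal length")
  if (n && any(object@abundance < 1L)) return("abundances must be >= 1")
  if (n && !all(nchar(object@sequence) == lengths(object@qualityProfile)))
    return("qualityProfile length must equal sequence length")
  if (length(object@map) && (any(object@map < 1L) || any(object@map > n)))
    return("map entries must index the unique sequences")
  TRUE
})

#' DadaResult: denoising output for one sample
#'
#' @slot asv data.frame with columns sequence, abundance (partition totals),
#'   one row per inferred sequence variant, ordered by decreasing abundance.
#' @slot assignment data.frame per unique sequence: sequence, abundance,
#'   partition (index into asv rows, NA when unassigned), lambda (error-model
#'   likelihood against its partition center).
#' @slot unassigned integer, number of reads set aside because no inferred
#'   variant could explain them (lambda 0 against every center) and their
#'   abundance did not permit a partition of their own.
#' @slot nread integer, number of input reads.
#' @slot opts list of inference parameters used.
#' @exportClass DadaResult
setClass("DadaResult",
  representation(asv = "data.frame", assignment = "data.frame",
                 unassigned = "integer", nread = "integer", opts = "list"))

#' AsvTable: samples x sequence-variant abundance matrix
#'
#' Integer abundances with one row per sample and one column per ASV
#' sequence (the column name is the sequence itself, as is conventional for
#' sequence tables). Columns are ordered by decreasing total abundance, ties
#' broken lexicographically.
#'
#' @slot table integer matrix, samples x ASVs, colnames are sequences.
#' @exportClass AsvTable
setClass("AsvTable", representation(table = "matrix"))

setValidity("AsvTable", function(object) {
  tb <- object@table
  if (length(tb)) {
    if (any(tb < 0)) return("abundances must be non-negative")
    if (anyDuplicated(colnames(tb))) return("ASV sequences must be unique")
    if (anyDuplicated(rownames(tb))) return("sample names must be unique")
  }
  TRUE
})

#' ErrorProfile: raw-read error tallies by type, position and quality
#'
#' Long-format tallies of substitution, insertion and deletion events by
#' 1-based read position and associated quality (deletions carry no quality),
#' together with the aligned-base totals needed to convert tallies to rates.
#'
#' @slot tallies data.frame: type, position, quality (NA for deletions), count.
#' @slot totalBases numeric, total aligned reference bases.
#' @slot positionTotals numeric, aligned reference bases by read position.
#' @slot excluded integer, reads excluded because no truth matched.
#' @slot nreads integer, reads profiled.
#' @exportClass ErrorProfile
setClass("ErrorProfile",
  representation(tallies = "data.frame", totalBases = "numeric",
                 positionTotals = "numeric", excluded = "integer",
                 nreads = "integer"))

#' CommunitySpec: ground-truth description of a simulated community
#'
#' @slot strains data.frame with one row per allele: strain, allele,
#'   sequence, copies (integer copy number of that allele within its genome),
#'   proportion (genome-level proportion of the strain; identical across a
#'   strain's alleles).
#' @slot subRate,insRate,delRate per-base marginal error rates.
#' @slot q93Mass probability a base receives the maximum quality score 93;
#'   remaining base qualities are uniform on [qLow, qHigh].
#' @slot qLow,qHigh range of the non-maximal quality scores.
#' @slot chimeraFraction fraction of reads formed as one-crossover mosaics.
#' @slot rcFraction fraction of reads emitted reverse-complemented.
#' @slot primers PrimerSpec attached to both ends of every read.
#' @slot seed integer seed making the simulation reproducible.
#' @exportClass CommunitySpec
setClass("CommunitySpec",
  representation(strains = "data.frame", subRate = "numeric",
                 insRate = "numeric", delRate = "numeric",
                 q93Mass = "numeric", qLow = "integer", qHigh = "integer",
                 chimeraFraction = "numeric", rcFraction = "numeric",
                 primers = "PrimerSpec", seed = "integer"))

setValidity("CommunitySpec", function(object) {
  st <- object@strains
  need <- c("strain", "allele", "sequence", "copies", "proportion")
  if (!all(need %in% names(st)))
    return("strains must have columns strain, allele, sequence, copies, proportion")
  if (any(st$copies < 1)) return("allele copy numbers must be >= 1")
  prop <- vapply(split(st$proportion, st$strain), `[`, numeric(1), 1L)
  if (abs(sum(prop) - 1) > 1e-8) return("genome proportions must sum to 1")
  for (r in c(object@subRate, object@insRate, object@delRate)) {
    if (r < 0 || r > 0.01) return("error rates must lie in [0, 0.01]")
  }
  if (object@chimeraFraction < 0 || object@chimeraFraction >= 1)
    return("chimeraFraction must lie in [0, 1)")
  if (object@rcFraction < 0 || object@rcFraction > 1)
    return("rcFraction must lie in [0, 1]")
  if (object@q93Mass < 0 || object@q93Mass > 1)
    return("q93Mass must lie in [0, 1]")
  TRUE
})
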