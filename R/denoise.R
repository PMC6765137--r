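# Divisive-partitioning inference of exact sequence variants under the
# quality-conditioned error model.

#' Dereplicate reads into unique sequences
#'
#' One entry per distinct sequence, with multiplicity and the position-wise
#' arithmetic mean of member qualities. Output is ordered by decreasing
#' abundance, ties broken lexicographically.
#'
#' @param reads an oriented, filtered \code{\link{QualReadSet-class}}.
#' @return a \code{\link{UniqueSequenceSet-class}}.
#' @examples
#' rs <- new("QualReadSet", id = c("a", "b", "c"),
#'           sequence = c("ACGT", "ACGT", "ACGG"),
#'           quality = list(rep(20L, 4), rep(40L, 4), rep(30L, 4)),
#'           orientation = rep("forward", 3))
#' abundances(dereplicate(rs))
#' @export
dereplicate <- function(reads) {
  stopifnot(is(reads, "QualReadSet"))
  n <- length(reads)
  if (n == 0)
    return(new("UniqueSequenceSet", sequence = character(),
               abundance = integer(), qualityProfile = list(),
               map = integer(), readQuality = list()))
  f <- factor(reads@sequence)
  ab <- tabulate(f)
  ord <- order(-ab, levels(f))
  pos <- integer(nlevels(f)); pos[ord] <- seq_along(ord)
  map <- pos[as.integer(f)]
  groups <- split(seq_len(n), map)
  qprof <- vector("list", nlevels(f))
  for (k in seq_along(groups)) {
    ix <- groups[[k]]
    if (length(ix) == 1L) qprof[[as.integer(names(groups)[k])]] <-
        as.numeric(reads@quality[[ix]])
    else qprof[[as.integer(names(groups)[k])]] <-
        colMeans(do.call(rbind, reads@quality[ix]))
  }
  new("UniqueSequenceSet", sequence = levels(f)[ord], abundance = ab[ord],
      qualityProfile = qprof, map = map, readQuality = reads@quality)
}

#' Kmer prefilter between two sequences
#'
#' Computes the kmer distance, \eqn{1 - overlap / \min(n_a, n_b)} where the
#' overlap is the multiset intersection of the two kmer arrays, and the
#' ungapped-shortcut flag: when the in-sequence-order kmer overlap equals the
#' multiset overlap, the ungapped (positional) alignment is taken to be the
#' optimal alignment and no dynamic programming is needed.
#'
#' @param a,b nucleotide strings, each at least \code{k} long.
#' @param k kmer size (default 8).
#' @return list with \code{kdist} in [0, 1] and \code{ungappedIsOptimal}.
#' @export
kmerScreen <- function(a, b, k = 8L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nchar(a) < k || nchar(b) < k)
    stop("sequences must be at least k long", call. = FALSE)
  ka <- C_kmer_arrays(c(a, b), as.integer(k))
  v <- C_kmer_compare(ka$ordered[[1]], ka$sorted[[1]],
                      ka$ordered[[2]], ka$sorted[[2]])
  list(kdist = v[1], ungappedIsOptimal = v[2] == 1)
}

#' Banded Needleman-Wunsch global alignment
#'
#' Optimal global alignment restricted to the diagonal band
#' \eqn{|i - j| \le band}; identical to the unconstrained alignment whenever
#' the optimal path stays inside the band. End gaps are penalized.
#' Tie-breaking is deterministic: diagonal, then up (gap in \code{b}), then
#' left (gap in \code{a}). When the length difference reaches the band the
#' alignment is refused and \code{NULL} is returned (the sequences are
#' treated as unrelated).
#'
#' @param a,b nucleotide strings.
#' @param band half-width of the diagonal band (default 32).
#' @param match,mismatch,gap scoring (defaults +5 / -4 / -8, no separate
#'   gap extension).
#' @return \code{NULL} if refused, else a list with \code{alignment}
#'   (character vector: gapped \code{a}, gapped \code{b}) and \code{score}.
#' @export
alignBanded <- function(a, b, band = 32L, match = 5L, mismatch = -4L,
                        gap = -8L) {
  r <- C_nwalign_banded(a, b, as.integer(match), as.integer(mismatch),
                        as.integer(gap), as.integer(band))
  if (isTRUE(r$refused)) return(NULL)
  list(alignment = c(r$al1, r$al2), score = r$score)
}

#' Error-model likelihood of a member sequence given a partition center
#'
#' \eqn{\lambda} is the product over alignment columns of
#' \eqn{p(\mathrm{observed} \mid \mathrm{true}, q)}, where the true base
#' comes from the center, the observed base and (rounded) quality from the
#' member, and indel columns contribute the model's quality-independent
#' indel rate.
#'
#' @param alignment character vector of length 2: gapped center, gapped
#'   member (e.g. from \code{\link{alignBanded}}).
#' @param quality integer/numeric vector of member qualities, one per
#'   (ungapped) member base; rounded to integers in [0, 93].
#' @param model an \code{\link{ErrorModel-class}}.
#' @return \eqn{\lambda} in (0, 1].
#' @export
computeLambda <- function(alignment, quality, model) {
  stopifnot(is(model, "ErrorModel"))
  q <- as.integer(round(quality))
  if (any(q < 0 | q > 93)) stop("qualities must lie in [0, 93]", call. = FALSE)
  at <- strsplit(alignment[1], "", fixed = TRUE)[[1]]
  ao <- strsplit(alignment[2], "", fixed = TRUE)[[1]]
  if (length(at) != length(ao))
    stop("alignment strings must have equal column count", call. = FALSE)
  if (sum(ao != "-") != length(q))
    stop("quality length must match the ungapped member sequence", call. = FALSE)
  both <- at != "-" & ao != "-"
  mpos <- cumsum(ao != "-")[both]
  tix <- match(at[both], .NT); oix <- match(ao[both], .NT)
  if (anyNA(tix) || anyNA(oix))
    stop("alignment contains non-ACGT characters", call. = FALSE)
  ll <- sum(log(model@rates[cbind(tix, oix, q[mpos] + 1L)])) +
    sum(!both) * log(model@indelRate)
  exp(ll)
}

#' Abundance p-value of a repeatedly observed sequence
#'
#' With \eqn{\mu = n_{center} \lambda}, the probability that a sequence
#' observed at least once is observed \eqn{\ge a} times under the error
#' model: \eqn{p_A = P(X \ge a \mid X \ge 1)} for \eqn{X \sim Poisson(\mu)}.
#' Numerically stable for \eqn{\mu \ll 1} (the regime of interest).
#'
#' @param lambda error-model likelihood in (0, 1].
#' @param nCenter reads in the partition able to generate the sequence.
#' @param a observed abundance (\eqn{\ge 1}).
#' @return \eqn{p_A} in (0, 1].
#' @export
abundancePValue <- function(lambda, nCenter, a) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(a < 1)) stop("abundance must be >= 1", call. = FALSE)
  mu <- nCenter * lambda
  p <- ifelse(a == 1, 1,
              stats::ppois(a - 1, mu, lower.tail = FALSE) / -expm1(-mu))
  pmin(p, 1)
}

# rates array in the memory order the C++ kernels expect
.rates_for_c <- function(model) as.numeric(aperm(model@rates, c(3, 2, 1)))

#' Infer exact sequence variants by divisive partitioning
#'
#' All unique sequences start in a single partition centered on the most
#' abundant. Repeatedly, the member with the smallest abundance p-value
#' (Bonferroni-corrected by the number of uniques) is promoted to a new
#' partition center if significant at \code{omegaA}; after each promotion,
#' every unique is reassigned to the partition whose center explains it with
#' the largest \eqn{\lambda}. Comparisons are skipped (\eqn{\lambda = 0})
#' when the kmer distance exceeds \code{kdistCutoff} or the banded alignment
#' is refused. Inference terminates when no member is significant.
#'
#' Sequences that no center can explain are promoted when their abundance is
#' at least 2 (the Poisson conditional p-value tends to 0); unexplainable
#' singletons are set aside and reported as unassigned rather than being
#' attributed to an arbitrary partition.
#'
#' @param uniques a \code{\link{UniqueSequenceSet-class}} (or a
#'   \code{\link{QualReadSet-class}}, which is dereplicated first).
#' @param model an \code{\link{ErrorModel-class}}.
#' @param omegaA promotion significance threshold on the Bonferroni-corrected
#'   abundance p-value (default 1e-40).
#' @param kdistCutoff kmer-distance screen (default 0.42).
#' @param band alignment band half-width (default 32).
#' @param kmerSize kmer size for the screen (default 8).
#' @param match,mismatch,gap alignment scoring.
#' @param verbose print promotions.
#' @return a \code{\link{DadaResult-class}}.
#' @export
runDada <- function(uniques, model, omegaA = 1e-40, kdistCutoff = 0.42,
                    band = 32L, kmerSize = 8L, match = 5L, mismatch = -4L,
                    gap = -8L, verbose = FALSE) {
  if (is(uniques, "QualReadSet")) uniques <- dereplicate(uniques)
  stopifnot(is(uniques, "UniqueSequenceSet"), is(model, "ErrorModel"))
  n <- length(uniques)
  if (n == 0) stop("no sequences to denoise", call. = FALSE)
  seqs <- uniques@sequence
  .stopifnot_acgt(seqs, "dereplicated sequence")
  ab <- uniques@abundance
  nread <- sum(ab)
  qint <- lapply(uniques@qualityProfile, function(x)
    pmin(pmax(as.integer(round(x)), 0L), 93L))
  ka <- C_kmer_arrays(seqs, as.integer(kmerSize))
  rates <- .rates_for_c(model)
  lam <- matrix(0, nrow = n, ncol = 0)

  add_center <- function(ci) {
    km <- C_kmer_compare_many(ka$ordered[[ci]], ka$sorted[[ci]],
                              ka$ordered, ka$sorted)
    col <- numeric(n)
    sel <- which(km[, 1] <= kdistCutoff)
    if (length(sel))
      col[sel] <- C_lambda_batch(seqs[ci], seqs[sel], qint[sel],
                                 km[sel, 2] == 1, as.integer(band),
                                 as.integer(match), as.integer(mismatch),
                                 as.integer(gap), rates, model@indelRate)
    cbind(lam, col)
  }

  centers <- 1L
  lam <- add_center(1L)
  repeat {
    # assignment: partition whose center yields the largest lambda
    part <- max.col(lam, ties.method = "first")
    best <- lam[cbind(seq_len(n), part)]
    part[best <= 0] <- NA_integer_
    part[centers] <- seq_along(centers)  # centers always own their partition
    pr <- vapply(seq_along(centers), function(k)
      sum(ab[!is.na(part) & part == k]), numeric(1))
    # abundance p-values (singletons can never be promoted)
    p <- rep(1, n)
    far <- is.na(part)
    p[far & ab >= 2L] <- 0
    ok <- !far & ab >= 2L
    if (any(ok)) {
      lamv <- lam[cbind(which(ok), part[ok])]
      zero <- lamv <= 0
      pv <- numeric(sum(ok))
      pv[zero] <- 0
      if (any(!zero))
        pv[!zero] <- abundancePValue(lamv[!zero], pr[part[which(ok)[!zero]]],
                                     ab[ok][!zero])
      p[ok] <- pv
    }
    p[centers] <- 1
    padj <- pmin(p * n, 1)
    padj[p == 0] <- 0
    cand <- setdiff(order(padj, -ab, seqs), centers)
    if (!length(cand) || length(centers) == n) break
    top <- cand[1]
    if (padj[top] >= omegaA) break
    if (verbose)
      message(sprintf("promoting unique %d (abundance %d, p_adj %.3g)",
                      top, ab[top], padj[top]))
    centers <- c(centers, top)
    lam <- add_center(top)
  }
  part <- max.col(lam, ties.method = "first")
  best <- lam[cbind(seq_len(n), part)]
  part[best <= 0] <- NA_integer_
  part[centers] <- seq_along(centers)
  asv_ab <- vapply(seq_along(centers), function(k)
    sum(ab[!is.na(part) & part == k]), numeric(1))
  ord <- order(-asv_ab, seqs[centers])
  asv <- data.frame(sequence = seqs[centers][ord],
                    abundance = as.integer(asv_ab[ord]),
                    stringsAsFactors = FALSE)
  remap <- integer(length(centers)); remap[ord] <- seq_along(ord)
  assignment <- data.frame(
    sequence = seqs, abundance = ab,
    partition = ifelse(is.na(part), NA_integer_, remap[part]),
    lambda = ifelse(is.na(part), 0, lam[cbind(seq_len(n), pmax(part, 1L))]),
    stringsAsFactors = FALSE)
  new("DadaResult", asv = asv, assignment = assignment,
      unassigned = as.integer(sum(ab[is.na(part)])),
      nread = as.integer(nread),
      opts = list(omegaA = omegaA, kdistCutoff = kdistCutoff, band = band,
                  kmerSize = kmerSize, match = match, mismatch = mismatch,
                  gap = gap))
}

#' Combine per-sample denoising results into an ASV table
#'
#' Columns are the union of ASVs across samples (absent entries are 0),
#' ordered by decreasing total abundance, ties broken lexicographically.
#'
#' @param results a named list of \code{\link{DadaResult-class}} objects
#'   (names are sample identifiers), or a single \code{DadaResult}.
#' @param sampleName sample identifier when a single result is given.
#' @return an \code{\link{AsvTable-class}}.
#' @export
makeAsvTable <- function(results, sampleName = "sample1") {
  if (is(results, "DadaResult"))
    results <- setNames(list(results), sampleName)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("every sample must be named", call. = FALSE)
  if (anyDuplicated(names(results)))
    stop("duplicate sample names", call. = FALSE)
  allseq <- unique(unlist(lapply(results, asvSequences), use.names = FALSE))
  tb <- matrix(0L, nrow = length(results), ncol = length(allseq),
               dimnames = list(names(results), allseq))
  for (s in names(results)) {
    a <- asvAbundances(results[[s]])
    tb[s, names(a)] <- as.integer(a)
  }
  if (ncol(tb)) {
    ord <- order(-colSums(tb), colnames(tb))
    tb <- tb[, ord, drop = FALSE]
  }
  new("AsvTable", table = tb)
}
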