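# Quality-conditioned error-model estimation, with the maximum quality score
# (93) estimated separately from the smooth fit over the rest of the
# distribution, and a self-consistency loop with the denoiser.

.RATE_FLOOR <- 1e-7
.RATE_CAP <- 0.25
.EMPTY_COUNTS <- function() array(0, dim = c(4L, 4L, 94L),
                                  dimnames = list(.NT, .NT, 0:93))

#' Construct an empty or prefilled TransitionCounts
#'
#' @param counts optional 4 x 4 x 94 array (true x observed x quality 0-93).
#' @param indels total indel events observed alongside the substitutions.
#' @param alignedBases total aligned (non-gap) bases observed.
#' @return a \code{\link{TransitionCounts-class}}.
#' @export
transitionCounts <- function(counts = NULL, indels = 0, alignedBases = 0) {
  if (is.null(counts)) counts <- .EMPTY_COUNTS()
  dimnames(counts) <- list(.NT, .NT, 0:93)
  new("TransitionCounts", counts = counts, indels = as.numeric(indels),
      alignedBases = as.numeric(alignedBases))
}

#' Merge transition counts
#'
#' Counts are additive under merging of datasets.
#'
#' @param e1,e2 \code{\link{TransitionCounts-class}} objects.
#' @export
setMethod("+", signature("TransitionCounts", "TransitionCounts"), function(e1, e2) {
  new("TransitionCounts", counts = e1@counts + e2@counts,
      indels = e1@indels + e2@indels,
      alignedBases = e1@alignedBases + e2@alignedBases)
})

#' Tally transitions from reads aligned to their assigned true sequences
#'
#' Every aligned (true base, read base, read quality) triple increments one
#' cell of the 4 x 4 x 94 count array. Insertion and deletion columns are
#' excluded from the substitution matrix and tallied separately (they inform
#' the quality-independent indel rate only).
#'
#' @param alignments list, one element per read: a character vector of length
#'   2 holding the gapped true sequence and the gapped read sequence.
#' @param qualities list of integer vectors: the read's per-base qualities
#'   (ungapped read coordinates).
#' @return a \code{\link{TransitionCounts-class}}.
#' @export
countTransitions <- function(alignments, qualities) {
  if (length(alignments) != length(qualities))
    stop("alignments and qualities must have equal length", call. = FALSE)
  acc <- numeric(4 * 4 * 94)
  indels <- 0; aligned <- 0
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    at <- strsplit(al[1], "", fixed = TRUE)[[1]]
    ao <- strsplit(al[2], "", fixed = TRUE)[[1]]
    if (length(at) != length(ao))
      stop("internal error: alignment strings of unequal column count", call. = FALSE)
    q <- qualities[[i]]
    if (sum(ao != "-") != length(q))
      stop("internal error: alignment columns inconsistent with read length",
           call. = FALSE)
    both <- at != "-" & ao != "-"
    mpos <- cumsum(ao != "-")
    tix <- match(at[both], .NT); oix <- match(ao[both], .NT)
    qv <- q[mpos[both]]
    ok <- !is.na(tix) & !is.na(oix)
    # linear index in R array order: true base fastest, then observed, then q
    idx <- qv[ok] * 16L + (oix[ok] - 1L) * 4L + tix[ok]
    acc <- acc + tabulate(idx, nbins = 4 * 4 * 94)
    indels <- indels + sum(!both)
    aligned <- aligned + sum(both)
  }
  transitionCounts(array(acc, dim = c(4, 4, 94)), indels, aligned)
}

# tricube-weighted local linear fit of y on x, evaluated at x0 (vectors)
.local_linear <- function(x, y, w0, x0, span = 0.5) {
  h <- max((max(x) - min(x)) * span, 2)
  vapply(x0, function(p) {
    d <- abs(x - p)
    w <- w0 * ifelse(d < h, (1 - (d / h)^3)^3, 0)
    if (sum(w > 0) < 1) {  # fall back to the nearest observations
      w <- w0 * (d <= min(d) + 1e-9)
    }
    xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
    sxx <- sum(w * (x - xm)^2)
    if (sxx < 1e-9) return(ym)
    b <- sum(w * (x - xm) * (y - ym)) / sxx
    ym + b * (p - xm)
  }, numeric(1))
}

#' Estimate quality-conditioned error rates from transition counts
#'
#' For qualities 0-92, each of the twelve error transitions is fitted by a
#' tricube-weighted local linear regression of log10(raw rate, with a
#' pseudocount on the error count) on quality, followed by an isotonic
#' non-increasing correction (pool-adjacent-violators via \code{isoreg}) and
#' flooring. The rate at the maximum quality score 93 is estimated
#' independently, from q = 93 observations only, as
#' (errors + pseudocount) / (total + 2 pseudocount) — the CCS quality-score
#' point mass at 93 does not extrapolate from the rest of the distribution.
#' Rates are normalized to sum to one over observed bases for every
#' (true base, quality).
#'
#' @param counts a \code{\link{TransitionCounts-class}} with at least one
#'   observation.
#' @param pseudocount added to error counts before the log transform
#'   (default 1).
#' @param span fraction of the observed quality range covered by the local
#'   regression window (default 0.5).
#' @return an \code{\link{ErrorModel-class}}.
#' @export
estimateRates <- function(counts, pseudocount = 1, span = 0.5) {
  stopifnot(is(counts, "TransitionCounts"))
  cc <- counts@counts
  tot <- apply(cc, c(1, 3), sum)  # 4 x 94: observations per (true, q)
  if (sum(tot) == 0) stop("cannot estimate rates from empty counts", call. = FALSE)
  rates <- array(0, dim = c(4L, 4L, 94L), dimnames = list(.NT, .NT, 0:93))
  for (t in 1:4) {
    for (o in setdiff(1:4, t)) {
      qs <- which(tot[t, 1:93] > 0) - 1L  # observed qualities <= 92
      fit <- if (length(qs) == 0) {
        # no sub-maximal observations for this true base: flat fallback from
        # the pooled (all-q) rate
        rep((sum(cc[t, o, ]) + pseudocount) / (sum(tot[t, ]) + 2 * pseudocount), 93)
      } else {
        n <- tot[t, qs + 1L]
        raw <- (cc[t, o, qs + 1L] + pseudocount) / n
        10^.local_linear(qs, log10(raw), w0 = n, x0 = 0:92, span = span)
      }
      # a higher quality must never imply a higher modeled error rate
      fit <- -stats::isoreg(0:92, -fit)$yf
      rates[t, o, 1:93] <- pmin(pmax(fit, .RATE_FLOOR), .RATE_CAP)
      # maximum quality score: estimated from q = 93 observations only
      t93 <- tot[t, 94]
      r93 <- if (t93 > 0) (cc[t, o, 94] + pseudocount) / (t93 + 2 * pseudocount)
             else rates[t, o, 93]
      rates[t, o, 94] <- min(max(r93, .RATE_FLOOR), .RATE_CAP)
    }
  }
  for (t in 1:4)
    rates[t, t, ] <- 1 - apply(rates[t, setdiff(1:4, t), , drop = FALSE], 3, sum)
  indel <- (counts@indels + pseudocount) / (counts@alignedBases + 2 * pseudocount)
  new("ErrorModel", rates = rates, indelRate = min(max(indel, .RATE_FLOOR), .RATE_CAP),
      totals = tot)
}

#' A maximally pessimistic starting error model
#'
#' Error rates independent of quality: each of the twelve error transitions
#' at \code{errorRate}, at every quality score including 93. Used to seed the
#' \code{\link{learnErrors}} self-consistency loop.
#'
#' @param errorRate flat per-transition error rate (default 2.5e-3, i.e. a
#'   total substitution rate of 7.5e-3 per base).
#' @param indelRate flat indel rate (default 2.5e-3).
#' @return an \code{\link{ErrorModel-class}}.
#' @export
naiveErrorModel <- function(errorRate = 2.5e-3, indelRate = 2.5e-3) {
  rates <- array(errorRate, dim = c(4L, 4L, 94L), dimnames = list(.NT, .NT, 0:93))
  for (t in 1:4) rates[t, t, ] <- 1 - 3 * errorRate
  new("ErrorModel", rates = rates, indelRate = indelRate,
      totals = matrix(0, 4, 94, dimnames = list(.NT, 0:93)))
}

#' Training-weighted aggregate substitution rate of a model
#'
#' Sum over (true base, quality) of the modeled total substitution
#' probability, weighted by the number of training observations in each cell
#' (uniform weights when the model carries no training totals).
#'
#' @param model an \code{\link{ErrorModel-class}}.
#' @return numeric scalar.
#' @export
aggregateSubstitutionRate <- function(model) {
  stopifnot(is(model, "ErrorModel"))
  perr <- 1 - apply(model@rates, 3, diag)  # 4 x 94: P(error | true, q)
  w <- model@totals
  if (sum(w) == 0) w <- matrix(1, 4, 94)
  sum(perr * w) / sum(w)
}

#' Learn the error model by alternating estimation and denoising
#'
#' Starting from a maximally pessimistic, quality-independent model, the
#' loop alternates: denoise with the current model; re-align every unique
#' sequence to its inferred partition center; re-tally transitions over all
#' member reads (with their own per-base qualities); re-estimate rates.
#' It stops when the maximum absolute change in log10 rate falls below
#' \code{tol}, or after \code{maxRounds} rounds. Reads that no inferred
#' sequence can explain (set aside by the denoiser) are excluded from the
#' tallies, as such reads are dominated by chimeras and contaminants.
#'
#' @param reads a filtered, oriented \code{\link{QualReadSet-class}}, or a
#'   \code{\link{UniqueSequenceSet-class}} from \code{\link{dereplicate}}.
#' @param maxRounds maximum alternation rounds (default 10).
#' @param tol convergence tolerance on the maximum absolute change in log10
#'   rate (default 0.05).
#' @param initModel starting model (default \code{\link{naiveErrorModel}()}).
#' @param ... passed to \code{\link{runDada}} (e.g. \code{omegaA},
#'   \code{band}, \code{kdistCutoff}).
#' @param verbose print per-round progress.
#' @return list with \code{model} (the converged
#'   \code{\link{ErrorModel-class}}) and \code{diagnostics} (data.frame with
#'   one row per round: round, maxDeltaLog10, nASV, converged).
#' @export
learnErrors <- function(reads, maxRounds = 10L, tol = 0.05,
                        initModel = naiveErrorModel(), ..., verbose = FALSE) {
  drp <- if (is(reads, "UniqueSequenceSet")) reads else dereplicate(reads)
  if (length(drp) == 0) stop("no reads to learn from", call. = FALSE)
  model <- initModel
  diag <- data.frame(round = integer(), maxDeltaLog10 = numeric(),
                     nASV = integer(), converged = logical())
  for (round in seq_len(maxRounds)) {
    dd <- runDada(drp, model, ...)
    counts <- .count_from_assignment(drp, dd, ...)
    newmodel <- estimateRates(counts)
    delta <- max(abs(log10(newmodel@rates / model@rates)))
    converged <- delta < tol
    diag <- rbind(diag, data.frame(round = round, maxDeltaLog10 = delta,
                                   nASV = nrow(dd@asv), converged = converged))
    if (verbose)
      message(sprintf("round %d: %d ASVs, max |delta log10 rate| = %.3g",
                      round, nrow(dd@asv), delta))
    model <- newmodel
    if (converged) break
  }
  list(model = model, diagnostics = diag)
}

# Tally transitions of every unique against its assigned partition center,
# over all member reads with their own qualities.
.count_from_assignment <- function(drp, dd, band = 32L, match = 5L,
                                   mismatch = -4L, gap = -8L, ...) {
  asgn <- dd@assignment
  acc <- numeric(4 * 4 * 94)
  indels <- 0; aligned <- 0
  for (k in seq_len(nrow(dd@asv))) {
    center <- dd@asv$sequence[k]
    uix <- which(!is.na(asgn$partition) & asgn$partition == k)
    if (!length(uix)) next
    als <- C_align_batch(center, drp@sequence[uix],
                         rep(FALSE, length(uix)), band, match, mismatch, gap)
    for (t in seq_along(uix)) {
      al <- als[[t]]
      if (is.null(al)) next
      at <- strsplit(al[1], "", fixed = TRUE)[[1]]
      ao <- strsplit(al[2], "", fixed = TRUE)[[1]]
      both <- at != "-" & ao != "-"
      mpos <- cumsum(ao != "-")[both]
      tix <- match(at[both], .NT); oix <- match(ao[both], .NT)
      base_idx <- (oix - 1L) * 4L + tix  # R array order: true fastest
      reads_r <- which(drp@map == uix[t])
      for (r in reads_r) {
        idx <- base_idx + drp@readQuality[[r]][mpos] * 16L
        acc <- acc + tabulate(idx, nbins = 4 * 4 * 94)
      }
      nr <- length(reads_r)
      indels <- indels + nr * sum(!both)
      aligned <- aligned + nr * sum(both)
    }
  }
  transitionCounts(array(acc, dim = c(4, 4, 94)), indels, aligned)
}

#' Serialize an error model to JSON
#'
#' Rates are keyed by transition (e.g. \code{"A>C"}) as vectors over quality
#' 0-93, alongside the indel rate and training totals.
#'
#' @param model an \code{\link{ErrorModel-class}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeErrorModel <- function(model, path) {
  stopifnot(is(model, "ErrorModel"))
  rr <- list()
  for (t in .NT) for (o in .NT)
    rr[[paste0(t, ">", o)]] <- unname(model@rates[t, o, ])
  obj <- list(rates = rr, indelRate = model@indelRate,
              totals = setNames(lapply(.NT, function(t) unname(model@totals[t, ])), .NT))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an error model from JSON
#'
#' @param path a file written by \code{\link{writeErrorModel}}.
#' @return an \code{\link{ErrorModel-class}}.
#' @export
readErrorModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- array(0, dim = c(4L, 4L, 94L), dimnames = list(.NT, .NT, 0:93))
  for (t in .NT) for (o in .NT) rates[t, o, ] <- obj$rates[[paste0(t, ">", o)]]
  totals <- do.call(rbind, obj$totals[.NT])
  dimnames(totals) <- list(.NT, 0:93)
  new("ErrorModel", rates = rates, indelRate = obj$indelRate, totals = totals)
}

#' Diagnostic plot of modeled error rates by quality score
#'
#' One panel per error transition; the line is the modeled rate, optional
#' points are the observed raw rates from a \code{TransitionCounts}.
#'
#' @param model an \code{\link{ErrorModel-class}}.
#' @param counts optional \code{\link{TransitionCounts-class}} to overlay.
#' @return a ggplot object.
#' @export
plotErrors <- function(model, counts = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotErrors requires the ggplot2 package", call. = FALSE)
  df <- do.call(rbind, lapply(1:4, function(t) do.call(rbind, lapply(
    setdiff(1:4, t), function(o) data.frame(
      transition = paste0(.NT[t], ">", .NT[o]), q = 0:93,
      rate = model@rates[t, o, ])))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[["q"]], y = .data[["rate"]])) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~transition) +
    ggplot2::labs(x = "quality score", y = "error rate")
  if (!is.null(counts)) {
    tot <- apply(counts@counts, c(1, 3), sum)
    obs <- do.call(rbind, lapply(1:4, function(t) do.call(rbind, lapply(
      setdiff(1:4, t), function(o) {
        qs <- which(tot[t, ] > 0) - 1L
        data.frame(transition = paste0(.NT[t], ">", .NT[o]), q = qs,
                   rate = counts@counts[t, o, qs + 1L] / tot[t, qs + 1L])
      }))))
    p <- p + ggplot2::geom_point(data = obs, alpha = 0.4)
  }
  p
}
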