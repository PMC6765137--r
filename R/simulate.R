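# Synthetic CCS-like mock-community generator with known ground truth.
# Emulates: multi-strain communities with multi-copy 16S alleles at integral
# within-genome ratios; per-base substitution/insertion/deletion errors
# conditioned on quality scores (with the CCS point mass at the maximum
# score of 93); one-crossover chimeric amplicons; random read orientation;
# attached degenerate primers.

.rand_seq <- function(len) paste(sample(.NT, len, replace = TRUE), collapse = "")

#' Generate reference alleles for simulated strains
#'
#' Each strain gets a random backbone; within a strain, allele 1 is the
#' backbone and each further allele carries \code{divergence} substitutions
#' at positions disjoint from its siblings' (so intragenomic alleles differ
#' pairwise by at least \code{divergence} substitutions). Independent random
#' backbones put inter-strain identity near 25%, far below the 95% ceiling
#' required of distinct strains.
#'
#' @param copiesPerStrain list of integer vectors, one per strain: the copy
#'   number of each allele (list names become strain names).
#' @param divergence substitutions distinguishing within-strain alleles
#'   (default 4; must be >= 1).
#' @param lengthRange backbone length range in nt (default c(1400, 1500),
#'   bracketing the primer-trimmed full-length 16S gene).
#' @param seed integer seed; the same seed reproduces the references.
#' @return data.frame with columns strain, allele, sequence, copies.
#' @export
makeAlleles <- function(copiesPerStrain, divergence = 4L,
                        lengthRange = c(1400L, 1500L), seed = 1L) {
  if (divergence < 1) stop("divergence must be >= 1", call. = FALSE)
  if (is.null(names(copiesPerStrain)))
    names(copiesPerStrain) <- sprintf("strain%02d", seq_along(copiesPerStrain))
  .with_seed(seed, {
    out <- list()
    for (s in names(copiesPerStrain)) {
      copies <- copiesPerStrain[[s]]
      nall <- length(copies)
      len <- sample(lengthRange[1]:lengthRange[2], 1)
      if ((nall - 1) * divergence > len)
        stop("divergence infeasible for the sequence length", call. = FALSE)
      backbone <- strsplit(.rand_seq(len), "", fixed = TRUE)[[1]]
      mutpos <- if (nall > 1)
        matrix(sample(len, (nall - 1) * divergence), nrow = nall - 1) else NULL
      for (j in seq_len(nall)) {
        sq <- backbone
        if (j > 1) {
          for (p in mutpos[j - 1, ]) {
            sq[p] <- sample(setdiff(.NT, sq[p]), 1)
          }
        }
        out[[length(out) + 1]] <- data.frame(
          strain = s, allele = sprintf("%s_allele%d", s, j),
          sequence = paste(sq, collapse = ""), copies = as.integer(copies[j]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Construct a community specification for simulation
#'
#' Default error rates are those measured for PacBio CCS full-length 16S
#' amplicon reads: substitutions 1.1e-4, insertions 2.2e-4, deletions
#' 1.0e-4 per base. The default quality model places 90% of bases at the
#' maximum score 93 with the remainder uniform on 30-92; substitution
#' probability scales with 10^(-q/30) so that quality-conditional error
#' rates are monotone while the marginal rate equals the configured value.
#'
#' @param alleles data.frame from \code{\link{makeAlleles}} (strain, allele,
#'   sequence, copies).
#' @param proportions named numeric: genome-level proportion per strain
#'   (summing to 1); defaults to equal proportions.
#' @param subRate,insRate,delRate marginal per-base error rates.
#' @param q93Mass probability of the maximum quality score (default 0.9).
#' @param qLow,qHigh range of sub-maximal qualities (default 30-92).
#' @param chimeraFraction fraction of reads built as one-crossover mosaics
#'   of two sampled templates (default 0.02).
#' @param rcFraction fraction of reads emitted reverse-complemented
#'   (default 0.5).
#' @param primers \code{\link{PrimerSpec-class}} attached to both ends.
#' @param seed integer seed for \code{\link{simulateReads}}.
#' @return a \code{\link{CommunitySpec-class}}.
#' @export
communitySpec <- function(alleles, proportions = NULL, subRate = 1.1e-4,
                          insRate = 2.2e-4, delRate = 1.0e-4, q93Mass = 0.9,
                          qLow = 30L, qHigh = 92L, chimeraFraction = 0.02,
                          rcFraction = 0.5, primers = primerSpec(),
                          seed = 1L) {
  strains <- unique(alleles$strain)
  if (is.null(proportions))
    proportions <- setNames(rep(1 / length(strains), length(strains)), strains)
  if (!all(strains %in% names(proportions)))
    stop("proportions must be named by strain", call. = FALSE)
  alleles$proportion <- as.numeric(proportions[alleles$strain])
  new("CommunitySpec", strains = alleles, subRate = subRate,
      insRate = insRate, delRate = delRate, q93Mass = q93Mass,
      qLow = as.integer(qLow), qHigh = as.integer(qHigh),
      chimeraFraction = chimeraFraction, rcFraction = rcFraction,
      primers = primers, seed = as.integer(seed))
}

#' An 8-strain even mock community (Zymo-like)
#'
#' Eight strains with the 16S copy numbers of the Zymo standard's bacteria
#' (4, 7, 7, 5, 4, 6, 6, 10), equimolar genomic proportions, and 29 distinct
#' alleles in total; the E. coli analogue carries five alleles at copies
#' 3:1:1:1:1 and the B. subtilis analogue a single allele at copy 10.
#'
#' @param seed integer seed (controls both the reference alleles and the
#'   reads simulated from the returned spec).
#' @param ... passed to \code{\link{communitySpec}} (e.g. error rates,
#'   \code{chimeraFraction}).
#' @return a \code{\link{CommunitySpec-class}}.
#' @export
zymoLikeSpec <- function(seed = 100L, ...) {
  copies <- list(
    P_aeruginosa  = c(1L, 1L, 1L, 1L),
    E_coli        = c(3L, 1L, 1L, 1L, 1L),
    S_enterica    = c(4L, 1L, 1L, 1L),
    L_fermentum   = c(1L, 1L, 1L, 1L, 1L),
    E_faecalis    = c(3L, 1L),
    S_aureus      = c(4L, 1L, 1L),
    L_monocytogenes = c(2L, 1L, 1L, 1L, 1L),
    B_subtilis    = c(10L))
  alleles <- makeAlleles(copies, seed = .derive_seed(seed, 1L))
  communitySpec(alleles, seed = seed, ...)
}

#' A 20-strain staggered mock community (HMP-like)
#'
#' Twenty strains with the 16S copy numbers of the HMP staggered mock
#' community (6, 2, 12, 7, 14, 3, 4, 7, 2, 6, 6, 4, 3, 4, 4, 6, 6, 7, 6, 4)
#' and genome proportions log-spaced over three orders of magnitude; the
#' E. coli analogue carries six alleles at copies 2:1:1:1:1:1.
#'
#' @inheritParams zymoLikeSpec
#' @return a \code{\link{CommunitySpec-class}}.
#' @export
hmpLikeSpec <- function(seed = 200L, ...) {
  copies <- list(
    A_baumannii      = c(3L, 2L, 1L),
    A_odontolyticus  = c(2L),
    B_cereus         = c(6L, 3L, 2L, 1L),
    B_vulgatus       = c(4L, 2L, 1L),
    C_beijerinckii   = c(8L, 4L, 2L),
    D_radiodurans    = c(2L, 1L),
    E_faecalis       = c(3L, 1L),
    E_coli           = c(2L, 1L, 1L, 1L, 1L, 1L),
    H_pylori         = c(1L, 1L),
    L_gasseri        = c(4L, 2L),
    L_monocytogenes  = c(2L, 1L, 1L, 1L, 1L),
    N_meningitidis   = c(3L, 1L),
    P_acnes          = c(3L),
    P_aeruginosa     = c(2L, 1L, 1L),
    R_sphaeroides    = c(1L, 1L, 1L, 1L),
    S_aureus         = c(4L, 1L, 1L),
    S_epidermidis    = c(5L, 1L),
    S_agalactiae     = c(4L, 2L, 1L),
    S_mutans         = c(3L, 3L),
    S_pneumoniae     = c(2L, 1L, 1L))
  alleles <- makeAlleles(copies, seed = .derive_seed(seed, 1L))
  prop <- 10^(-3 * (seq_along(copies) - 1) / (length(copies) - 1))
  prop <- setNames(prop / sum(prop), names(copies))
  communitySpec(alleles, proportions = prop, seed = seed, ...)
}

# expand a degenerate IUPAC primer to one concrete realization
.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

.expand_iupac <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) {
    s <- .IUPAC_SETS[[c]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

#' Simulate CCS-like amplicon reads from a community specification
#'
#' Templates are sampled with probability proportional to genome proportion
#' times allele copy number. Per-base qualities are drawn from the spec's
#' quality model; substitutions occur with probability scaled by
#' \eqn{10^{-q/30}} so that the marginal rate equals the configured
#' substitution rate; insertions and deletions are placed uniformly at the
#' configured rates (an inserted base carries its own drawn quality;
#' deletions carry none). A configured fraction of reads is built as
#' one-crossover mosaics of two sampled templates, and a configured fraction
#' is emitted reverse-complemented. Concrete realizations of the degenerate
#' primers are attached at both ends.
#'
#' @param spec a \code{\link{CommunitySpec-class}}.
#' @param nReads number of reads.
#' @return list with \code{reads} (a \code{\link{QualReadSet-class}},
#'   orientation unknown) and \code{truth} (data.frame: id, strain, allele,
#'   chimera, parentA, parentB, nSub, nIns, nDel).
#' @export
simulateReads <- function(spec, nReads) {
  stopifnot(is(spec, "CommunitySpec"))
  validObject(spec)
  st <- spec@strains
  w <- st$proportion * st$copies
  w <- w / sum(w)
  qpool <- spec@qLow:spec@qHigh
  wq <- function(q) 10^(-q / 30)
  Ew <- spec@q93Mass * wq(93) + (1 - spec@q93Mass) * mean(wq(qpool))
  subScale <- spec@subRate / Ew
  fwd <- spec@primers@forward; rvp <- spec@primers@reverse

  .with_seed(spec@seed, {
    tidx <- sample.int(nrow(st), nReads, replace = TRUE, prob = w)
    chim <- runif(nReads) < spec@chimeraFraction
    rc <- runif(nReads) < spec@rcFraction
    tmpl_chars <- lapply(st$sequence, function(s) strsplit(s, "", fixed = TRUE)[[1]])

    draw_q <- function(n) {
      q <- rep(93L, n)
      low <- runif(n) >= spec@q93Mass
      q[low] <- sample(qpool, sum(low), replace = TRUE)
      q
    }

    ids <- sprintf("read%06d", seq_len(nReads))
    seqs <- character(nReads); quals <- vector("list", nReads)
    parentB <- rep(NA_character_, nReads)
    nSub <- integer(nReads); nIns <- integer(nReads); nDel <- integer(nReads)
    code <- c(A = 0L, C = 1L, G = 2L, T = 3L)

    for (r in seq_len(nReads)) {
      tpl <- tmpl_chars[[tidx[r]]]
      if (chim[r]) {
        j <- sample.int(nrow(st), 1, prob = w)
        frac <- runif(1, 0.2, 0.8)
        other <- tmpl_chars[[j]]
        xa <- max(1L, round(frac * length(tpl)))
        xb <- min(length(other), max(1L, round(frac * length(other))) + 1L)
        tpl <- c(tpl[seq_len(xa)], other[xb:length(other)])
        parentB[r] <- st$allele[j]
      }
      L <- length(tpl)
      del <- runif(L) < spec@delRate
      bases <- tpl[!del]
      nb <- length(bases)
      q <- draw_q(nb)
      sub <- runif(nb) < subScale * wq(q)
      if (any(sub)) {
        bc <- code[bases[sub]]
        bases[sub] <- .NT[((bc + sample.int(3, sum(sub), replace = TRUE)) %% 4L) + 1L]
      }
      ins <- which(runif(nb) < spec@insRate)
      if (length(ins)) {
        newb <- sample(.NT, length(ins), replace = TRUE)
        newq <- draw_q(length(ins))
        ord <- order(c(seq_len(nb), ins + 0.5))
        bases <- c(bases, newb)[ord]
        q <- c(q, newq)[ord]
      }
      fprimer <- .expand_iupac(fwd)
      rprimer <- C_revcomp(.expand_iupac(rvp))
      pq1 <- draw_q(nchar(fprimer)); pq2 <- draw_q(nchar(rprimer))
      s <- paste0(fprimer, paste(bases, collapse = ""), rprimer)
      qv <- c(pq1, q, pq2)
      if (rc[r]) { s <- C_revcomp(s); qv <- rev(qv) }
      seqs[r] <- s; quals[[r]] <- qv
      nSub[r] <- sum(sub); nIns[r] <- length(ins); nDel[r] <- sum(del)
    }
    truth <- data.frame(id = ids, strain = st$strain[tidx],
                        allele = st$allele[tidx], chimera = chim,
                        parentA = ifelse(chim, st$allele[tidx], NA_character_),
                        parentB = parentB, nSub = nSub, nIns = nIns,
                        nDel = nDel, stringsAsFactors = FALSE)
    reads <- new("QualReadSet", id = ids, sequence = seqs, quality = quals,
                 orientation = rep("unknown", nReads))
    list(reads = reads, truth = truth)
  })
}
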