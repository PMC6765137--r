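# Strain binning by integral ratios, full-complement consensus
# classification, sub-region extraction.

# exhaustive small-case oracle: try every partition of ASVs into bins and
# every copy assignment (copies 1..maxc); fewest bins first, then smallest
# total deviation (all partitions here bin every ASV)
oracle_bins <- function(ab, copyNumber, tol = 0.2, maxc = 12) {
  n <- length(ab)
  best <- NULL
  # enumerate set partitions via restricted growth strings
  rgs <- function(prefix, mx) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (v in 1:(mx + 1)) out <- c(out, rgs(c(prefix, v), max(mx, v)))
    out
  }
  for (part in rgs(integer(0), 0)) {
    total <- 0; ok <- TRUE
    for (b in unique(part)) {
      ix <- which(part == b)
      cands <- unlist(lapply(ab[ix], function(a) a / 1:maxc))
      bestbin <- Inf
      for (g in cands) {
        cp <- round(ab[ix] / g)
        if (any(cp < 1)) next
        if (!is.null(copyNumber) && sum(cp) != copyNumber) next
        g2 <- sum(ab[ix]) / sum(cp)
        dev <- abs(ab[ix] / g2 - round(ab[ix] / g2))
        if (any(round(ab[ix] / g2) < 1) || any(dev > tol)) next
        bestbin <- min(bestbin, sum(dev))
      }
      if (!is.finite(bestbin)) { ok <- FALSE; break }
      total <- total + bestbin
    }
    nb <- length(unique(part))
    if (ok && (is.null(best) || nb < best$nbins ||
               (nb == best$nbins && total < best$cost - 1e-12)))
      best <- list(cost = total, nbins = nb, part = part)
  }
  best
}

test_that("binStrains recovers canonical integral copy patterns", {
  b1 <- binStrains(c(300, 100, 100, 100, 100), copyNumber = 7)
  expect_true(all(b1$bin == 1))
  expect_equal(b1$copies, c(3L, 1L, 1L, 1L, 1L))
  b2 <- binStrains(c(200, 100, 100, 100, 100, 100), copyNumber = 7)
  expect_true(all(b2$bin == 1))
  expect_equal(b2$copies, c(2L, 1L, 1L, 1L, 1L, 1L))
})

test_that("well-separated abundance scales produce separate strain bins", {
  ab <- c(3000, 1000, 1000, 1000, 1000, 30, 10, 10, 10, 10)
  bins <- binStrains(ab, copyNumber = 7)
  expect_equal(length(unique(bins$bin)), 2L)
  expect_equal(bins$copies, rep(c(3L, 1L, 1L, 1L, 1L), 2))
  expect_true(all(bins$bin[1:5] == bins$bin[1]))
  expect_true(all(bins$bin[6:10] == bins$bin[6]))
})

test_that("binStrains matches the exhaustive oracle on exact integral inputs", {
  set.seed(51)
  for (rep in 1:6) {
    cn <- sample(4:8, 1)
    # random copy composition summing to cn
    cp <- c()
    left <- cn
    while (left > 0) { k <- sample(seq_len(min(left, 4)), 1); cp <- c(cp, k); left <- left - k }
    unit <- sample(50:400, 1)
    ab <- cp * unit
    got <- binStrains(ab, copyNumber = cn)
    orc <- oracle_bins(ab, cn)
    expect_false(is.null(orc))
    expect_equal(sum(got$deviation), orc$cost, tolerance = 1e-9)
    expect_equal(length(unique(got$bin)), orc$nbins)
    expect_equal(sort(got$copies), sort(cp))
  }
})

test_that("noisy but integral abundances still bin within tolerance", {
  set.seed(52)
  ab <- c(3, 1, 1, 1, 1) * 100 + c(9, -5, 4, -7, 6)
  bins <- binStrains(ab, copyNumber = 7)
  expect_equal(bins$copies, c(3L, 1L, 1L, 1L, 1L))
  expect_true(all(bins$bin == 1L))
  expect_true(all(bins$deviation <= 0.2))
  # an ASV incompatible with the main bin's scale cannot join it; with a
  # known copy number it can only stand as a putative one-allele strain
  bins2 <- binStrains(c(300, 100, 100, 100, 100, 47), copyNumber = 7)
  expect_equal(bins2$copies[1:5], c(3L, 1L, 1L, 1L, 1L))
  expect_true(all(bins2$bin[1:5] == bins2$bin[1]))
  expect_true(is.na(bins2$bin[6]) || bins2$bin[6] != bins2$bin[1])
})

test_that("consensusClassify reproduces the serotype consensus logic", {
  # 14 max-occurrence accessions; 12 annotated, 2 missing -> unanimous call
  hits <- do.call(rbind, lapply(sprintf("asv%d", 1:4), function(a)
    data.frame(asv = a, accession = sprintf("acc%02d", 1:14),
               serotype = c(rep("O157:H7", 12), NA, NA))))
  # one stray accession hitting a single ASV must not enter the consensus set
  hits <- rbind(hits, data.frame(asv = "asv1", accession = "stray",
                                 serotype = "O26:H11"))
  out <- consensusClassify(hits, "serotype")
  expect_equal(out$classification, "O157:H7")
  expect_equal(out$supportingAccessions, 14L)
  expect_equal(out$maxOccurrence, 4L)
  # all metadata missing -> unclassified; conflicting -> ambiguous
  h2 <- data.frame(asv = "a", accession = c("x", "y"),
                   serotype = c(NA, NA))
  expect_equal(consensusClassify(h2, "serotype")$classification, "unclassified")
  h3 <- data.frame(asv = "a", accession = c("x", "y"),
                   serotype = c("K12", "O157:H7"))
  expect_equal(consensusClassify(h3, "serotype")$classification, "ambiguous")
  expect_error(consensusClassify(h3[0, ], "serotype"), "empty")
})

test_that("consensusClassify is invariant to ASV order and duplicate hit sets", {
  hits <- data.frame(
    asv = rep(c("a", "b", "c"), each = 3),
    accession = c("p", "q", "r", "p", "q", "s", "p", "t", "u"),
    strain = c("K12", "K12", NA, "K12", "K12", "B", "K12", NA, "C"))
  base <- consensusClassify(hits, "strain")
  shuffled <- consensusClassify(hits[sample(nrow(hits)), ], "strain")
  expect_equal(base$classification, shuffled$classification)
  expect_equal(base$classification, "K12")
  # duplicating an ASV's identical hit set renames it but keeps the call
  dup <- rbind(hits, transform(hits[hits$asv == "a", ], asv = "a2"))
  expect_equal(consensusClassify(dup, "strain")$classification, "K12")
})

test_that("full-complement consensus is at least as specific as representative", {
  # representative (most abundant ASV alone) reaches a broader accession set
  hits <- data.frame(
    asv = c(rep("rep", 3), rep("minor", 2)),
    accession = c("broad1", "broad2", "k12acc", "k12acc", "other"),
    strain = c(NA, NA, "K12", "K12", NA))
  full <- consensusClassify(hits, "strain")
  reponly <- consensusClassify(hits[hits$asv == "rep", ], "strain")
  expect_equal(full$classification, "K12")
  expect_equal(reponly$classification, "K12")
  expect_lte(full$supportingAccessions, reponly$supportingAccessions + 2)
})

test_that("extractSubregion returns the region strictly between the primers", {
  set.seed(53)
  region <- rand_dna(250)
  v34 <- v3v4Primers()
  fwd <- "CCTACGGGAGGCAGCAG"   # concrete realization of the degenerate 341F
  rev3 <- as.character(reverseComplement("GACTACTAGGGTATCTAATCC"))
  full <- paste0(rand_dna(300), fwd, region, rev3, rand_dna(400))
  expect_equal(extractSubregion(full, v34), region)
  expect_null(extractSubregion(rand_dna(500), v34))
  # alleles identical inside the region but differing outside extract equally
  full2 <- paste0(rand_dna(280), fwd, region, rev3, rand_dna(390))
  expect_identical(extractSubregion(full, v34), extractSubregion(full2, v34))
})
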