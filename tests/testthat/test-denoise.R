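# Dereplication, kmer screen, banded alignment, lambda, abundance p-value,
# divisive partitioning, ASV table assembly.

test_that("dereplicate collapses sequences with mean quality profiles", {
  rs <- make_reads(c("ACGT", "ACGT", "ACGG"),
                   list(c(20L, 20L, 20L, 20L), c(40L, 40L, 40L, 40L),
                        c(30L, 30L, 30L, 30L)))
  drp <- dereplicate(rs)
  expect_identical(sequences(drp), c("ACGT", "ACGG"))
  expect_identical(unname(abundances(drp)), c(2L, 1L))
  expect_equal(drp@qualityProfile[[1]], rep(30, 4))
  expect_identical(drp@map, c(1L, 1L, 2L))
  # abundance ties break lexicographically
  drp2 <- dereplicate(make_reads(c("TTTT", "AAAA")))
  expect_identical(sequences(drp2), c("AAAA", "TTTT"))
  expect_length(dereplicate(new("QualReadSet")), 0)
})

test_that("kmerScreen matches brute-force kmer counting", {
  set.seed(21)
  a <- rand_dna(100)
  expect_equal(kmerScreen(a, a, 8), list(kdist = 0, ungappedIsOptimal = TRUE))
  # one substitution at position 50: 8 of 93 kmers change, ungapped optimal
  b <- a
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 50, 50))[1]
  ks <- kmerScreen(a, b, 8)
  orc <- oracle_kdist(a, b, 8)
  expect_equal(ks$kdist, orc$kdist)
  expect_equal(ks$kdist, 8 / 93, tolerance = 1e-12)
  expect_true(ks$ungappedIsOptimal)
  # one deletion: order is broken
  d <- paste0(substr(a, 1, 49), substr(a, 51, 100))
  ksd <- kmerScreen(a, d, 8)
  expect_false(ksd$ungappedIsOptimal)
  expect_equal(ksd$kdist, oracle_kdist(a, d, 8)$kdist)
  expect_error(kmerScreen(a, b, 0), "positive")
})

test_that("kmerScreen agrees with the oracle on random divergent pairs", {
  set.seed(22)
  for (i in 1:25) {
    a <- rand_dna(sample(60:120, 1))
    b <- if (i %% 2) rand_dna(nchar(a)) else {
      x <- strsplit(a, "")[[1]]
      x[sample(length(x), 3)] <- sample(c("A", "C", "G", "T"), 3, TRUE)
      paste(x, collapse = "")
    }
    got <- kmerScreen(a, b, 6)
    want <- oracle_kdist(a, b, 6)
    expect_equal(got$kdist, want$kdist, tolerance = 1e-12)
    expect_equal(got$ungappedIsOptimal, want$ungapped)
  }
})

test_that("banded alignment equals the unbanded oracle when the band covers", {
  expect_equal(alignBanded("ACGTACGT", "ACGTACGT")$alignment,
               c("ACGTACGT", "ACGTACGT"))
  al <- alignBanded("ACGTACGT", "ACGACGT", band = 16)
  orc <- oracle_nw("ACGTACGT", "ACGACGT")
  expect_equal(al$score, orc$score)
  expect_equal(al$alignment, orc$alignment)
  # refusal when the length difference reaches the band
  expect_null(alignBanded(rand_dna(100), rand_dna(60), band = 32))
})

test_that("computeLambda follows closed forms and monotonicity", {
  s <- 1 - 3 * 2.5e-3
  m <- naiveErrorModel()
  L <- 40
  seqc <- rand_dna(L)
  al <- c(seqc, seqc)
  expect_equal(computeLambda(al, rep(93, L), m), s^L, tolerance = 1e-12)
  # one A->C mismatch swaps one self factor for one error factor
  pos <- regexpr("A", seqc)[1]
  mem <- seqc; substr(mem, pos, pos) <- "C"
  lam2 <- computeLambda(c(seqc, mem), rep(93, L), m)
  expect_equal(lam2, s^(L - 1) * 2.5e-3, tolerance = 1e-12)
  # an error at higher quality is less likely under a monotone model
  cc <- array(0, dim = c(4, 4, 94))
  for (t in 1:4) {
    for (q in c(20, 60)) {
      cc[t, t, q + 1] <- c(1000, 100000)[match(q, c(20, 60))]
      cc[t, setdiff(1:4, t), q + 1] <- c(30, 3)[match(q, c(20, 60))]
    }
  }
  mono <- estimateRates(transitionCounts(cc))
  q <- rep(60L, L); q2 <- q;
  qlow <- q; qlow[pos] <- 20L
  expect_gt(computeLambda(c(seqc, mem), qlow, m = mono),
            computeLambda(c(seqc, mem), q, m = mono))
  expect_error(computeLambda(al, rep(95, L), m), "0, 93")
})

test_that("abundancePValue matches direct Poisson series summation", {
  expect_equal(abundancePValue(0.5, 10, 1), 1)
  # mu = 1, a = 10 against the series oracle
  expect_equal(abundancePValue(0.1, 10, 10), oracle_pois_cond(1, 10),
               tolerance = 1e-12)
  for (mu in c(1e-8, 1e-4, 0.1, 1, 5, 50)) {
    for (a in c(1, 2, 3, 10, 40)) {
      got <- abundancePValue(mu / 1000, 1000, a)
      want <- oracle_pois_cond(mu, a)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # non-increasing in abundance at fixed mu
  ps <- abundancePValue(rep(1e-3, 5), 1000, c(1, 2, 3, 5, 8))
  expect_true(all(diff(ps) <= 0))
  expect_error(abundancePValue(0, 10, 2), "positive")
})

test_that("runDada resolves an error-free mixture exactly, conserving reads", {
  set.seed(23)
  K <- 4
  truths <- replicate(K, rand_dna(250))
  counts <- c(100, 50, 25, 20)
  rs <- make_reads(rep(truths, counts))
  dd <- runDada(dereplicate(rs), naiveErrorModel())
  expect_setequal(asvSequences(dd), truths)
  expect_equal(sort(unname(asvAbundances(dd))), sort(counts))
  expect_equal(sum(asvAbundances(dd)) + dd@unassigned, length(rs))
  # every ASV is verbatim an observed read sequence
  expect_true(all(asvSequences(dd) %in% sequences(rs)))
})

test_that("omegaA = 0 suppresses all promotions", {
  set.seed(24)
  truths <- replicate(3, rand_dna(200))
  rs <- make_reads(rep(truths, c(50, 30, 20)))
  dd <- runDada(dereplicate(rs), naiveErrorModel(), omegaA = 0)
  expect_equal(nrow(dd@asv), 1L)
})

test_that("denoising is deterministic: identical inputs, identical output", {
  set.seed(25)
  spec <- zymoLikeSpec(seed = 7, chimeraFraction = 0)
  sim <- simulateReads(spec, 400)
  drp <- dereplicate(prepareReads(sim$reads)$reads)
  d1 <- runDada(drp, naiveErrorModel())
  d2 <- runDada(drp, naiveErrorModel())
  expect_identical(d1@asv, d2@asv)
  expect_identical(d1@assignment, d2@assignment)
})

test_that("makeAsvTable unions ASVs across samples with stable ordering", {
  set.seed(26)
  x <- rand_dna(60); y <- rand_dna(60); z <- rand_dna(60)
  mk_dd <- function(seqs, ab) {
    rs <- make_reads(rep(seqs, ab))
    runDada(dereplicate(rs), naiveErrorModel())
  }
  d1 <- mk_dd(c(x, y), c(10, 5))
  d2 <- mk_dd(c(x, z), c(3, 7))
  tab <- makeAsvTable(list(s1 = d1, s2 = d2))
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(asvTable(tab)["s1", x], 10L)
  expect_equal(asvTable(tab)["s2", x], 3L)
  expect_equal(asvTable(tab)["s1", z], 0L)
  # columns ordered by total abundance
  expect_equal(colnames(asvTable(tab))[1], x)
  expect_error(makeAsvTable(list(s1 = d1, s1 = d2)), "duplicate")
  single <- makeAsvTable(d1, "only")
  expect_equal(dim(single), c(1L, 2L))
})
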