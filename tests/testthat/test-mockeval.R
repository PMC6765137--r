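# Genomic abundances, integral-ratio accuracy calls, error profiling,
# rarefaction, replicate concordance.

test_that("genomic abundance and normalized ratios follow the copy-number rule", {
  expect_equal(genomicAbundance(c(300, 100, 100, 100, 100), 7), 100)
  expect_equal(genomicAbundance(40, 10), 4)
  expect_equal(genomicAbundance(0, 4), 0)
  expect_error(genomicAbundance(c(10), 0), "copyNumber")
  expect_equal(normalizedRatios(c(300, 100, 100, 100, 100), 100),
               c(3, 1, 1, 1, 1))
  expect_equal(normalizedRatios(rep(7, 4), 7), rep(1, 4))
  # scale invariance
  ab <- c(120, 41, 39)
  g <- genomicAbundance(ab, 5)
  expect_equal(normalizedRatios(ab * 13, g * 13), normalizedRatios(ab, g))
  expect_error(normalizedRatios(c(1, 2), 0), "positive")
})

test_that("integral ratios compose back to exact copy numbers", {
  copies <- c(3, 1, 1, 1, 1)
  unit <- 250
  ab <- copies * unit
  g <- genomicAbundance(ab, sum(copies))
  expect_equal(normalizedRatios(ab, g), copies)
})

test_that("integralRatioCheck applies the +/-0.2 integer rule", {
  chk <- integralRatioCheck(c(1.15, 1.45, 0.1, 2.0, 3.19))
  expect_equal(chk$nearest, c(1L, 1L, 0L, 2L, 3L))
  expect_equal(chk$deviation, c(0.15, 0.45, 0.1, 0, 0.19), tolerance = 1e-12)
  expect_equal(chk$pass, c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("assessAccuracy classifies exact, ratio-supported and unsupported ASVs", {
  set.seed(41)
  a1 <- rand_dna(100); a2 <- rand_dna(100); a3 <- rand_dna(100)
  a4 <- rand_dna(100); a5 <- rand_dna(100)
  asv <- data.frame(
    sequence = c(a1, a2, a3, a4, a5),
    abundance = c(300, 100, 205, 160, 50),
    strain = c("X", "X", "X", "Y", NA),
    stringsAsFactors = FALSE)
  refs <- data.frame(strain = c("X", "X"), sequence = c(a1, a2))
  cns <- c(X = 6, Y = 1)
  out <- assessAccuracy(asv, refs, cns)
  v <- setNames(out$verdicts$verdict, out$verdicts$sequence)
  expect_equal(unname(v[c(a1, a2)]), c("exact", "exact"))
  # a3: ratio 205/(605/6) = 2.03 -> integral, multi-allele bin -> supported
  expect_equal(unname(v[a3]), "supported")
  # a4: single-allele bin without reference match -> unsupported
  expect_equal(unname(v[a4]), "unsupported")
  expect_equal(unname(v[a5]), "unsupported")
  expect_equal(unname(out$summary), c(2L, 1L, 2L))
})

test_that("profileErrors is exact on constructed reads", {
  set.seed(42)
  truth <- rand_dna(300)
  # identical read: zero tallies
  p0 <- profileErrors(make_reads(truth), truth)
  expect_equal(sum(p0@tallies$count), 0)
  expect_equal(p0@totalBases, 300)
  # one inserted base at position 101 with quality 17
  ins_read <- paste0(substr(truth, 1, 100), "A", substr(truth, 101, 300))
  q <- rep(93L, 301); q[101] <- 17L
  p1 <- profileErrors(make_reads(ins_read, list(q)), truth)
  tl <- p1@tallies
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$type, "insertion")
  expect_equal(tl$quality, 17L)
  expect_true(tl$position %in% 100:102)  # homopolymer context can shift it
  # one substitution and one deletion
  sub_read <- truth; substr(sub_read, 50, 50) <-
    setdiff(c("A", "C", "G", "T"), substr(truth, 50, 50))[1]
  del_read <- paste0(substr(truth, 1, 199), substr(truth, 201, 300))
  p2 <- profileErrors(make_reads(c(sub_read, del_read)), truth)
  by_type <- tapply(p2@tallies$count, p2@tallies$type, sum)
  expect_equal(as.numeric(by_type[c("substitution", "deletion")]), c(1, 1))
  expect_true(all(is.na(p2@tallies$quality[p2@tallies$type == "deletion"])))
  # reads matching no truth are excluded and counted
  p3 <- profileErrors(make_reads(rand_dna(300)), truth)
  expect_equal(p3@excluded, 1L)
  expect_equal(p3@nreads, 0L)
})

test_that("reads are attributed to their best-scoring truth", {
  set.seed(43)
  t1 <- rand_dna(200)
  t2 <- t1
  for (p in c(30, 90, 150)) substr(t2, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(t1, p, p))[1]
  # a read equal to t2 must align to t2 (zero errors), not t1 (three)
  prof <- profileErrors(make_reads(t2), c(t1, t2))
  expect_equal(sum(prof@tallies$count), 0)
})

test_that("rarefaction preserves totals, is reproducible, keeps proportions", {
  counts <- c(a = 12000, b = 6000, c = 2000)
  sub <- rarefyCounts(counts, 10000, seed = 5)
  expect_equal(sum(sub), 10000)
  expect_true(all(sub <= counts))
  expect_identical(sub, rarefyCounts(counts, 10000, seed = 5))
  expect_identical(rarefyCounts(counts, sum(counts)), counts)
  expect_error(rarefyCounts(counts, 1e9), "depth")
  # expected proportions preserved over 200 seeds
  props <- sapply(1:200, function(s) rarefyCounts(counts, 2000, seed = s) / 2000)
  p0 <- counts / sum(counts)
  se <- sqrt(p0 * (1 - p0) / 2000 / 200)
  expect_true(all(abs(rowMeans(props) - p0) < 3 * se + 1e-3))
})

test_that("replicate concordance counts shared observations and correlates", {
  set.seed(44)
  seqs <- replicate(3, rand_dna(50))
  tA <- new("AsvTable", table = matrix(
    c(10L, 5L, 0L, 8L, 0L, 2L), nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), seqs)))
  same <- replicateConcordance(tA, tA)
  expect_equal(same$aOnly + same$bOnly, 0)
  expect_equal(same$pearson, 1)
  # doubling abundances keeps correlation 1 and all observations shared
  tB <- new("AsvTable", table = tA@table * 2L)
  dbl <- replicateConcordance(tA, tB)
  expect_equal(dbl$shared, 4)
  expect_equal(dbl$pearson, 1)
  # disjoint ASV sets share nothing
  tC <- new("AsvTable", table = matrix(
    c(3L, 1L), nrow = 2, dimnames = list(c("s1", "s2"), rand_dna(50))))
  dis <- replicateConcordance(tA, tC)
  expect_equal(dis$shared, 0)
  # disjoint sample sets are a validation error
  tD <- new("AsvTable", table = matrix(1L, 1, 1, dimnames = list("zz", seqs[1])))
  expect_error(replicateConcordance(tA, tD), "share no samples")
})
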