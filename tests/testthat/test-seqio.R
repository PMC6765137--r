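# FASTQ I/O, primer matching/orientation/removal, quality filtering.

test_that("FASTQ round-trip preserves sequences and qualities, including Q93", {
  set.seed(1)
  seqs <- vapply(c(40, 55, 70), rand_dna, character(1))
  quals <- lapply(nchar(seqs), function(L) sample(0:93, L, replace = TRUE))
  quals[[1]][1:5] <- 93L  # the CCS maximum maps to ASCII '~'
  rs <- make_reads(seqs, quals, ids = c("a", "b", "c"))
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeAmpliconFastq(rs, tf)
  back <- readAmpliconFastq(tf)
  expect_identical(unname(sequences(back)), seqs)
  expect_identical(lapply(unname(qualities(back)), as.integer), quals)
  expect_identical(names(back), c("a", "b", "c"))
  expect_true(all(orientations(back) == "unknown"))
})

test_that("quality character '~' decodes to 93 and empty files to empty sets", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "~~!I"), tf)
  rs <- readAmpliconFastq(tf)
  expect_identical(qualities(rs)[["r1"]], c(93L, 93L, 0L, 40L))
  tf2 <- withr::local_tempfile(fileext = ".fastq")
  file.create(tf2)
  expect_length(readAmpliconFastq(tf2), 0)
})

test_that("malformed records raise a parse error naming the record", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@good", "ACGT", "+", "IIII",
               "@bad1", "ACGTACGTAC", "+", "IIIIIIIII"), tf)  # 10 bases, 9 quals
  expect_error(readAmpliconFastq(tf), "bad1")
})

test_that("matchPrimer implements IUPAC-set containment with tie-breaking", {
  # 27F primer against a concrete E. coli-style realization: zero mismatches
  hit <- matchPrimer("AGRGTTYGATYMTGGCTCAG", "AGAGTTTGATCATGGCTCAG", 0)
  expect_identical(hit, list(offset = 1L, mismatches = 0L))
  expect_null(matchPrimer("ACGT", "AGGT", 0))
  expect_identical(matchPrimer("ACGT", "AGGT", 1),
                   list(offset = 1L, mismatches = 1L))
  # fewest mismatches wins over the earlier offset
  expect_identical(matchPrimer("ACGT", "AGGTACGT", 1)$offset, 5L)
  # ties -> smallest offset
  expect_identical(matchPrimer("ACGT", "ACGTACGT", 0)$offset, 1L)
  expect_error(matchPrimer("ACXT", "ACGTACGT"), "IUPAC")
})

test_that("matchPrimer agrees with set-expansion oracle on random windows", {
  set.seed(7)
  primer <- "AGRGTTYGATYMTGGCTCAG"
  for (i in 1:50) {
    s <- rand_dna(60)
    hit <- matchPrimer(primer, s, maxMismatch = 6)
    mms <- vapply(1:(60 - 19), function(off)
      oracle_mismatches(primer, substr(s, off, off + 19)), numeric(1))
    if (is.null(hit)) {
      expect_gt(min(mms), 6)
    } else {
      expect_equal(hit$mismatches, min(mms))
      expect_equal(hit$offset, which.min(mms))
    }
  }
})

test_that("removePrimers orients, trims, and tallies dropped reads", {
  set.seed(2)
  primers <- primerSpec()
  insert <- rand_dna(60)
  fwd <- "AGAGTTTGATCATGGCTCAG"
  rev3 <- as.character(reverseComplement("AGTTACCTTGTTACGACTT"))
  amplicon <- paste0(fwd, insert, rev3)
  q <- seq_len(nchar(amplicon)) %% 94
  rs <- make_reads(
    c(amplicon, as.character(reverseComplement(amplicon)), insert),
    list(as.integer(q), as.integer(rev(q)), rep(93L, 60)))
  out <- removePrimers(rs, primers)
  expect_identical(unname(out$tally[c("kept", "no_forward_primer")]), c(2L, 1L))
  expect_identical(unname(sequences(out$reads)), c(insert, insert))
  expect_identical(unname(orientations(out$reads)), c("forward", "rc"))
  # oriented qualities track the oriented bases exactly
  expect_identical(out$reads@quality[[1]], out$reads@quality[[2]])
})

test_that("removePrimers output is invariant under reverse-complementing inputs", {
  set.seed(3)
  primers <- primerSpec()
  mk <- function() paste0("AGGGTTCGATCATGGCTCAG", rand_dna(80),
                          as.character(reverseComplement("GGCTACCTTGTTACGACTT")))
  seqs <- replicate(20, mk())
  quals <- lapply(nchar(seqs), function(L) sample(0:93, L, replace = TRUE))
  rs <- make_reads(seqs, quals)
  flip <- sample(20, 9)
  seqs2 <- seqs; quals2 <- quals
  seqs2[flip] <- as.character(reverseComplement(seqs[flip]))
  quals2[flip] <- lapply(quals[flip], rev)
  rs2 <- make_reads(seqs2, quals2)
  a <- removePrimers(rs, primers); b <- removePrimers(rs2, primers)
  expect_identical(a$tally, b$tally)
  expect_identical(sort(sequences(a$reads)), sort(sequences(b$reads)))
})

test_that("orientation idempotence: re-attaching primers and re-trimming is stable", {
  set.seed(4)
  primers <- primerSpec()
  seqs <- replicate(10, paste0("AGAGTTTGATCATGGCTCAG", rand_dna(70),
                               as.character(reverseComplement("AGCTACCTTGTTACGACTT"))))
  rs <- make_reads(seqs)
  once <- removePrimers(rs, primers)
  reattached <- make_reads(
    paste0("AGAGTTTGATCATGGCTCAG", sequences(once$reads),
           as.character(reverseComplement("AGCTACCTTGTTACGACTT"))))
  twice <- removePrimers(reattached, primers)
  expect_identical(unname(sequences(twice$reads)), unname(sequences(once$reads)))
})

test_that("filterReads applies length, N and expected-error rules with full tally", {
  p <- filterParams(minLen = 1000, maxLen = 1600, maxEE = 2, maxN = 0)
  r_short <- rand_dna(900)
  r_good <- rand_dna(1500)
  r_n <- paste0(substr(r_good, 1, 750), "N", substr(r_good, 752, 1500))
  rs <- make_reads(c(r_short, r_good, r_n))
  out <- filterReads(rs, p)
  expect_identical(unname(sequences(out$reads)), r_good)
  expect_identical(unname(out$tally[c("too_short", "too_many_n", "kept")]),
                   c(1L, 1L, 1L))
  expect_equal(sum(out$tally[-1]), length(rs))
  # EE of an all-Q93 1500-mer is ~7.5e-7; at Q10 each base contributes 0.1
  expect_lt(expectedErrors(make_reads(r_good)), 1e-6)
  bad <- make_reads(r_good, list(rep(10L, 1500)))
  expect_identical(unname(filterReads(bad, p)$tally[["too_many_ee"]]), 1L)
})

test_that("empty inputs pass through primer removal and filtering", {
  empty <- new("QualReadSet")
  expect_length(removePrimers(empty)$reads, 0)
  expect_length(filterReads(empty)$reads, 0)
})
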