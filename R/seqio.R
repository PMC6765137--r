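# Sequence I/O, primer detection/orientation/removal, quality filtering.

#' Construct a PrimerSpec
#'
#' The default primer pair is the full-length 16S rRNA gene pair
#' 27F \code{AGRGTTYGATYMTGGCTCAG} / 1492R \code{RGYTACCTTGTTACGACTT}.
#' Primer matching is ungapped: CCS error rates make indel-tolerant primer
#' matching unnecessary, and ungapped semantics keep trim offsets exact.
#'
#' @param forward,reverse IUPAC primer strings (each 5'->3' on its own strand).
#' @param maxMismatch maximum mismatches tolerated per primer (default 2).
#' @param searchWindow bases from each read end searched for the primer;
#'   defaults to the longer primer length + 10.
#' @return a \code{\link{PrimerSpec-class}} object.
#' @examples
#' primerSpec()
#' @export
primerSpec <- function(forward = "AGRGTTYGATYMTGGCTCAG",
                       reverse = "RGYTACCTTGTTACGACTT",
                       maxMismatch = 2L, searchWindow = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (is.null(searchWindow))
    searchWindow <- max(nchar(forward), nchar(reverse)) + 10L
  new("PrimerSpec", forward = forward, reverse = reverse,
      maxMismatch = as.integer(maxMismatch),
      searchWindow = as.integer(searchWindow))
}

#' Construct read-filtering parameters
#'
#' Defaults bracket the ~1.5 kb full-length 16S amplicon: length in
#' [1000, 1600] nt, at most 2 expected errors, no N bases.
#'
#' @param minLen,maxLen bounds (nt) on the primer-trimmed read length.
#' @param maxEE maximum expected errors, \eqn{\sum_i 10^{-q_i/10}}.
#' @param maxN maximum number of N bases.
#' @return a \code{\link{FilterParams-class}} object.
#' @export
filterParams <- function(minLen = 1000L, maxLen = 1600L, maxEE = 2, maxN = 0L) {
  new("FilterParams", minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      maxEE = as.numeric(maxEE), maxN = as.integer(maxN))
}

#' Read amplicon reads from a FASTQ file
#'
#' Qualities are decoded as Sanger/Phred+33, supporting scores up to 93
#' (ASCII \code{~}), as emitted for PacBio CCS reads. Record order is
#' preserved and orientation is set to \code{"unknown"}.
#'
#' @param path path to a FASTQ file.
#' @return a \code{\link{QualReadSet-class}}.
#' @export
readAmpliconFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(new("QualReadSet"))
  parsed <- tryCatch({
    # Biostrings warns about dropping (empty) metadata columns on conversion
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(quals = as.list(methods::as(Biostrings::quality(x), "IntegerList")),
         seqs = as.character(x), nm = names(x))
  }, error = function(e) .fastq_diagnose(path, conditionMessage(e)))
  n <- length(parsed$seqs)
  quals <- parsed$quals
  seqs <- parsed$seqs
  x <- parsed
  ids <- if (is.null(parsed$nm)) sprintf("read%06d", seq_len(n)) else
    sub("\\s.*$", "", parsed$nm)
  bad <- which(nchar(seqs) != lengths(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ record '%s': %d bases but %d quality scores",
                 ids[bad[1]], nchar(seqs[bad[1]]), lengths(quals)[bad[1]]),
         call. = FALSE)
  new("QualReadSet", id = unname(ids), sequence = unname(seqs),
      quality = unname(quals),
      orientation = rep("unknown", n))
}

# identify the offending record so parse errors are actionable
.fastq_diagnose <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  nrec <- length(lines) %/% 4
  for (i in seq_len(nrec)) {
    seq <- lines[4 * i - 2]; qual <- lines[4 * i]
    id <- sub("^@", "", sub("\\s.*$", "", lines[4 * i - 3]))
    if (is.na(qual) || nchar(seq) != nchar(qual))
      stop(sprintf("malformed FASTQ record '%s': %d bases but %d quality scores",
                   id, nchar(seq), ifelse(is.na(qual), 0L, nchar(qual))),
           call. = FALSE)
  }
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ file (truncated record at end): ", path, call. = FALSE)
  stop("failed to parse FASTQ file ", path, ": ", msg, call. = FALSE)
}

#' Write amplicon reads to a FASTQ file
#'
#' Sanger/Phred+33 encoding; quality 93 is written as ASCII \code{~}.
#'
#' @param reads a \code{\link{QualReadSet-class}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAmpliconFastq <- function(reads, path) {
  stopifnot(is(reads, "QualReadSet"))
  d <- Biostrings::DNAStringSet(setNames(reads@sequence, reads@id))
  q <- Biostrings::PhredQuality(vapply(reads@quality, .qual_to_ascii, character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(d, q)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (names become headers).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Best ungapped match of a degenerate primer within a sequence
#'
#' A position matches when the IUPAC set of the primer code contains the
#' read base; up to \code{maxMismatch} violations are allowed and indels are
#' not. Among qualifying offsets the fewest-mismatch one is returned, ties
#' broken by the smallest offset.
#'
#' @param primer IUPAC primer string.
#' @param sequence nucleotide string to search.
#' @param maxMismatch maximum mismatches allowed.
#' @return \code{NULL} if no qualifying offset, else a list with
#'   \code{offset} (1-based) and \code{mismatches}.
#' @examples
#' matchPrimer("AGRGTTYGATYMTGGCTCAG", "AGAGTTTGATCATGGCTCAG", 0)
#' @export
matchPrimer <- function(primer, sequence, maxMismatch = 2L) {
  primer <- toupper(primer)
  if (!nzchar(primer) || !.is_iupac(primer))
    stop("primer must be a non-empty IUPAC nucleotide string", call. = FALSE)
  if (nchar(primer) > nchar(sequence))
    stop("primer longer than sequence", call. = FALSE)
  hit <- C_iupac_best(primer, toupper(sequence), as.integer(maxMismatch),
                      0L, nchar(sequence) - nchar(primer))
  if (hit[1] < 0) return(NULL)
  list(offset = hit[1] + 1L, mismatches = hit[2])
}

#' Detect, orient by, and remove a primer pair
#'
#' Each read is kept when the forward primer is found near its 5' end and the
#' reverse complement of the reverse primer near its 3' end — searching the
#' read as-is first and then its reverse complement (with qualities reversed
#' in step), since CCS reads arrive in a mixture of orientations. Primers and
#' everything outside them are trimmed. When both orientations match fully,
#' the orientation with fewer total primer mismatches wins and ties are
#' dropped as ambiguous. Reads lacking a primer in both orientations are
#' dropped and tallied.
#'
#' @param reads a \code{\link{QualReadSet-class}}.
#' @param primers a \code{\link{PrimerSpec-class}}.
#' @return list with \code{reads} (kept, oriented, trimmed QualReadSet) and
#'   \code{tally} (named integer: input, kept, no_forward_primer,
#'   no_reverse_primer, ambiguous_orientation).
#' @export
removePrimers <- function(reads, primers = primerSpec()) {
  stopifnot(is(reads, "QualReadSet"), is(primers, "PrimerSpec"))
  n <- length(reads)
  tally <- c(input = n, kept = 0L, no_forward_primer = 0L,
             no_reverse_primer = 0L, ambiguous_orientation = 0L)
  if (n == 0) return(list(reads = reads, tally = tally))
  m <- C_remove_primers(reads@sequence, primers@forward, primers@reverse,
                        primers@maxMismatch, primers@searchWindow)
  status <- m[, 1]
  tally["kept"] <- sum(status == 0L)
  tally["no_forward_primer"] <- sum(status == 1L)
  tally["no_reverse_primer"] <- sum(status == 2L)
  tally["ambiguous_orientation"] <- sum(status == 3L)
  keep <- which(status == 0L)
  if (!length(keep)) {
    return(list(reads = new("QualReadSet"), tally = tally))
  }
  seqs <- character(length(keep)); quals <- vector("list", length(keep))
  orient <- ifelse(m[keep, 2] == 1L, "rc", "forward")
  for (t in seq_along(keep)) {
    r <- keep[t]
    s <- reads@sequence[r]; q <- reads@quality[[r]]
    if (m[r, 2] == 1L) { s <- C_revcomp(s); q <- rev(q) }
    seqs[t] <- substr(s, m[r, 3] + 1L, m[r, 4])
    quals[[t]] <- q[seq.int(m[r, 3] + 1L, length.out = m[r, 4] - m[r, 3])]
  }
  list(reads = new("QualReadSet", id = reads@id[keep], sequence = seqs,
                   quality = quals, orientation = orient),
       tally = tally)
}

#' Expected errors of each read
#'
#' \eqn{EE = \sum_i 10^{-q_i/10}} over a read's quality scores.
#'
#' @param reads a \code{\link{QualReadSet-class}}.
#' @return numeric vector of expected error counts.
#' @export
expectedErrors <- function(reads) {
  vapply(reads@quality, function(q) sum(10^(-q / 10)), numeric(1))
}

#' Filter reads on length, N content and expected errors
#'
#' A read is kept iff \code{minLen <= length <= maxLen}, it contains at most
#' \code{maxN} N bases, and its expected errors do not exceed \code{maxEE}.
#'
#' @param reads a primer-trimmed \code{\link{QualReadSet-class}}.
#' @param params a \code{\link{FilterParams-class}}.
#' @return list with \code{reads} (kept subset) and \code{tally}
#'   (input, kept, too_short, too_long, too_many_n, too_many_ee; a read is
#'   tallied under the first criterion it fails).
#' @export
filterReads <- function(reads, params = filterParams()) {
  stopifnot(is(reads, "QualReadSet"), is(params, "FilterParams"))
  len <- nchar(reads@sequence)
  nN <- nchar(gsub("[^N]", "", reads@sequence))
  ee <- expectedErrors(reads)
  fail <- character(length(reads))
  fail[ee > params@maxEE] <- "too_many_ee"
  fail[nN > params@maxN] <- "too_many_n"
  fail[len > params@maxLen] <- "too_long"
  fail[len < params@minLen] <- "too_short"
  keep <- fail == ""
  tally <- c(input = length(reads), kept = sum(keep),
             too_short = sum(fail == "too_short"),
             too_long = sum(fail == "too_long"),
             too_many_n = sum(fail == "too_many_n"),
             too_many_ee = sum(fail == "too_many_ee"))
  list(reads = reads[which(keep)], tally = tally)
}

#' Primer removal and filtering in one step
#'
#' Convenience wrapper: \code{\link{removePrimers}} then
#' \code{\link{filterReads}}, with a combined tally.
#'
#' @param reads a \code{\link{QualReadSet-class}}.
#' @param primers a \code{\link{PrimerSpec-class}}.
#' @param params a \code{\link{FilterParams-class}}.
#' @return list with \code{reads} and \code{tally}.
#' @export
prepareReads <- function(reads, primers = primerSpec(), params = filterParams()) {
  rp <- removePrimers(reads, primers)
  fl <- filterReads(rp$reads, params)
  list(reads = fl$reads, tally = c(rp$tally, fl$tally[-1]))
}
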