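# Internal helpers shared across modules.

.NT <- c("A", "C", "G", "T")
.IUPAC_CHARS <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N")

.is_iupac <- function(x) {
  all(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in% .IUPAC_CHARS)
}

#' Reverse complement of nucleotide strings
#'
#' Handles IUPAC degenerate codes; case is preserved for A/C/G/T.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
reverseComplement <- function(x) C_revcomp(x)

# quality integer vector -> Phred+33 string and back
.qual_to_ascii <- function(q) intToUtf8(q + 33L)
.ascii_to_qual <- function(s) utf8ToInt(s) - 33L

.stopifnot_acgt <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop(sprintf("%s contains characters other than A/C/G/T (first offender: %s)",
                 what, seqs[which(bad)[1]]), call. = FALSE)
  invisible(TRUE)
}

.n_errors <- function(tc) {
  off <- !diag(4)
  sum(apply(tc@counts, 3, function(m) sum(m[off])))
}

# deterministic seed derivation, kept below 2^31
.derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
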