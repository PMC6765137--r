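# Independent oracles, deliberately written without reference to the
# package's implementation paths.

# Unbanded Needleman-Wunsch, full DP, same scoring contract:
# end gaps penalized; tie preference diagonal > up (gap in b) > left (gap in a).
oracle_nw <- function(a, b, match = 5, mismatch = -4, gap = -8) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  S[1, ] <- (0:m) * gap; P[1, ] <- 3L
  S[, 1] <- (0:n) * gap; P[, 1] <- 2L
  P[1, 1] <- 0L
  for (i in 1:n) for (j in 1:m) {
    d <- S[i, j] + if (A[i] == B[j]) match else mismatch
    u <- S[i, j + 1] + gap
    l <- S[i + 1, j] + gap
    best <- max(d, u, l)
    S[i + 1, j + 1] <- best
    P[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
  }
  i <- n + 1; j <- m + 1; a1 <- c(); a2 <- c()
  while (i > 1 || j > 1) {
    p <- P[i, j]
    if (p == 1L) { a1 <- c(A[i - 1], a1); a2 <- c(B[j - 1], a2); i <- i - 1; j <- j - 1 }
    else if (p == 2L) { a1 <- c(A[i - 1], a1); a2 <- c("-", a2); i <- i - 1 }
    else { a1 <- c("-", a1); a2 <- c(B[j - 1], a2); j <- j - 1 }
  }
  list(score = S[n + 1, m + 1],
       alignment = c(paste(a1, collapse = ""), paste(a2, collapse = "")))
}

# Direct Poisson series summation for P(X >= a | X >= 1); the denominator
# 1 - P(X = 0) is evaluated with expm1 to stay accurate for mu << 1
oracle_pois_cond <- function(mu, a) {
  if (a == 1) return(1)
  ks <- a:(a + 2000)
  num <- sum(exp(-mu + ks * log(mu) - lgamma(ks + 1)))
  num / -expm1(-mu)
}

# Brute-force kmer multiset overlap and in-order overlap
oracle_kmers <- function(s, k) {
  n <- nchar(s) - k + 1
  vapply(seq_len(n), function(i) substr(s, i, i + k - 1), character(1))
}
oracle_kdist <- function(a, b, k) {
  ka <- oracle_kmers(a, k); kb <- oracle_kmers(b, k)
  ta <- table(ka); tb <- table(kb)
  shared <- intersect(names(ta), names(tb))
  ov <- sum(pmin(ta[shared], tb[shared]))
  m <- min(length(ka), length(kb))
  ordered <- sum(ka[seq_len(m)] == kb[seq_len(m)])
  list(kdist = 1 - ov / m, ungapped = ordered == ov)
}

# IUPAC set expansion for primer-matching checks
oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))
oracle_mismatches <- function(primer, window) {
  pc <- strsplit(primer, "")[[1]]; wc <- strsplit(window, "")[[1]]
  sum(!mapply(function(p, w) w %in% oracle_iupac[[p]], pc, wc))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(L) rep(93L, L))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  new("QualReadSet", id = ids, sequence = seqs, quality = quals,
      orientation = rep("unknown", length(seqs)))
}
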