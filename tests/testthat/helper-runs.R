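# Shared simulation runs, computed lazily once per test session. The Zymo-
# and HMP-scale pipeline runs are used by several acceptance checks.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

zymo_run <- function() cached("zymo", {
  spec <- zymoLikeSpec(seed = 101)
  sim <- simulateReads(spec, 10000)
  res <- denoisePipeline(sim$reads)
  list(spec = spec, sim = sim, res = res)
})

hmp_run <- function() cached("hmp", {
  spec <- hmpLikeSpec(seed = 11)
  sim <- simulateReads(spec, 20000)
  res <- denoisePipeline(sim$reads)
  list(spec = spec, sim = sim, res = res)
})

# per-strain ASV:genome integral-ratio deviations for a pipeline result
ratio_deviations <- function(spec, table) {
  st <- spec@strains
  ab <- asvTable(table)[1, ]
  ix <- match(names(ab), st$sequence)
  out <- data.frame(sequence = names(ab), strain = st$strain[ix],
                    abundance = as.numeric(ab), ratio = NA_real_,
                    deviation = NA_real_, stringsAsFactors = FALSE)
  for (s in unique(stats::na.omit(out$strain))) {
    sel <- which(out$strain == s)
    cn <- sum(st$copies[st$strain == s])
    ga <- genomicAbundance(out$abundance[sel], cn)
    out$ratio[sel] <- normalizedRatios(out$abundance[sel], ga)
    out$deviation[sel] <- abs(out$ratio[sel] - round(out$ratio[sel]))
  }
  out
}
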