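# Generics, accessors and show methods.

#' @rdname QualReadSet-class
#' @param x,object a \code{QualReadSet}
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname QualReadSet-class
#' @export
setGeneric("qualities", function(x) standardGeneric("qualities"))
#' @rdname QualReadSet-class
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname QualReadSet-class
#' @export
setMethod("sequences", "QualReadSet", function(x) setNames(x@sequence, x@id))
#' @rdname QualReadSet-class
#' @export
setMethod("qualities", "QualReadSet", function(x) setNames(x@quality, x@id))
#' @rdname QualReadSet-class
#' @export
setMethod("orientations", "QualReadSet", function(x) setNames(x@orientation, x@id))
#' @rdname QualReadSet-class
#' @export
setMethod("length", "QualReadSet", function(x) length(x@sequence))
#' @rdname QualReadSet-class
#' @export
setMethod("names", "QualReadSet", function(x) x@id)

#' @rdname QualReadSet-class
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "QualReadSet", function(x, i, j, ..., drop = TRUE) {
  new("QualReadSet", id = x@id[i], sequence = x@sequence[i],
      quality = x@quality[i], orientation = x@orientation[i])
})

setMethod("show", "QualReadSet", function(object) {
  cat("QualReadSet with", length(object), "reads\n")
  if (length(object)) {
    len <- nchar(object@sequence)
    cat(sprintf("  length: %d-%d nt (median %d)\n",
                min(len), max(len), as.integer(stats::median(len))))
    cat("  orientation:",
        paste(names(table(object@orientation)), table(object@orientation),
              sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "PrimerSpec", function(object) {
  cat("PrimerSpec\n  forward:", object@forward, "\n  reverse:", object@reverse,
      "\n  maxMismatch:", object@maxMismatch,
      " searchWindow:", object@searchWindow, "\n")
})

setMethod("show", "FilterParams", function(object) {
  cat(sprintf("FilterParams: length [%d, %d], maxEE %g, maxN %d\n",
              object@minLen, object@maxLen, object@maxEE, object@maxN))
})

#' @rdname ErrorModel-class
#' @param x,object an \code{ErrorModel}
#' @export
setGeneric("errorRates", function(x) standardGeneric("errorRates"))
#' @rdname ErrorModel-class
#' @export
setGeneric("indelRate", function(x) standardGeneric("indelRate"))
#' @rdname ErrorModel-class
#' @export
setMethod("errorRates", "ErrorModel", function(x) x@rates)
#' @rdname ErrorModel-class
#' @export
setMethod("indelRate", "ErrorModel", function(x) x@indelRate)

setMethod("show", "ErrorModel", function(object) {
  agg <- aggregateSubstitutionRate(object)
  cat("ErrorModel (4 x 4 x 94 quality-conditioned transition rates)\n")
  cat(sprintf("  aggregate substitution rate (training-weighted): %.3g\n", agg))
  cat(sprintf("  indel rate: %.3g\n", object@indelRate))
})

setMethod("show", "TransitionCounts", function(object) {
  cat(sprintf("TransitionCounts: %s aligned bases, %s errors, %s indels\n",
              format(object@alignedBases), format(.n_errors(object)),
              format(object@indels)))
})

#' @rdname UniqueSequenceSet-class
#' @param x,object a \code{UniqueSequenceSet}
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname UniqueSequenceSet-class
#' @export
setMethod("abundances", "UniqueSequenceSet", function(x)
  setNames(x@abundance, x@sequence))
#' @rdname UniqueSequenceSet-class
#' @export
setMethod("sequences", "UniqueSequenceSet", function(x) x@sequence)
#' @rdname UniqueSequenceSet-class
#' @export
setMethod("length", "UniqueSequenceSet", function(x) length(x@sequence))

setMethod("show", "UniqueSequenceSet", function(object) {
  cat("UniqueSequenceSet:", length(object), "unique sequences from",
      sum(object@abundance), "reads\n")
})

#' @rdname DadaResult-class
#' @param x,object a \code{DadaResult}
#' @export
setGeneric("asvSequences", function(x) standardGeneric("asvSequences"))
#' @rdname DadaResult-class
#' @export
setGeneric("asvAbundances", function(x) standardGeneric("asvAbundances"))
#' @rdname DadaResult-class
#' @export
setMethod("asvSequences", "DadaResult", function(x) x@asv$sequence)
#' @rdname DadaResult-class
#' @export
setMethod("asvAbundances", "DadaResult", function(x)
  setNames(x@asv$abundance, x@asv$sequence))

setMethod("show", "DadaResult", function(object) {
  cat("DadaResult:", nrow(object@asv), "sequence variants from",
      object@nread, "reads")
  if (object@unassigned > 0)
    cat(" (", object@unassigned, " unexplained reads set aside)", sep = "")
  cat("\n")
})

#' @rdname AsvTable-class
#' @param x,object an \code{AsvTable}
#' @export
setGeneric("asvTable", function(x) standardGeneric("asvTable"))
#' @rdname AsvTable-class
#' @export
setMethod("asvTable", "AsvTable", function(x) x@table)
#' @rdname AsvTable-class
#' @export
setMethod("asvSequences", "AsvTable", function(x) colnames(x@table))
#' @rdname AsvTable-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname AsvTable-class
#' @export
setMethod("sampleNames", "AsvTable", function(x) rownames(x@table))
#' @rdname AsvTable-class
#' @export
setMethod("dim", "AsvTable", function(x) dim(x@table))

setMethod("show", "AsvTable", function(object) {
  cat("AsvTable:", nrow(object@table), "samples x", ncol(object@table),
      "ASVs;", sum(object@table), "reads\n")
})

setMethod("show", "ErrorProfile", function(object) {
  rates <- aggregateErrorRates(object)
  cat("ErrorProfile over", object@nreads, "reads (",
      format(object@totalBases), "aligned reference bases )\n")
  cat(sprintf("  substitution %.3g, insertion %.3g, deletion %.3g per base\n",
              rates[["substitution"]], rates[["insertion"]], rates[["deletion"]]))
  if (object@excluded > 0)
    cat("  excluded (no matching truth):", object@excluded, "reads\n")
})

setMethod("show", "CommunitySpec", function(object) {
  st <- object@strains
  cat("CommunitySpec:", length(unique(st$strain)), "strains,",
      nrow(st), "alleles\n")
  cat(sprintf("  rates: sub %.2g, ins %.2g, del %.2g; chimera %.2g; rc %.2g\n",
              object@subRate, object@insRate, object@delRate,
              object@chimeraFraction, object@rcFraction))
})
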