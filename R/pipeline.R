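# End-to-end convenience wrapper: filter -> learn errors -> denoise ->
# remove chimeras, for a single sample.

#' Run the full denoising pipeline on one sample
#'
#' Primer removal and orientation, expected-error filtering, error-model
#' learning by self-consistency, sequence-variant inference, and de novo
#' bimera removal.
#'
#' @param reads a \code{\link{QualReadSet-class}} (raw, primers attached),
#'   or a path to a FASTQ file.
#' @param primers a \code{\link{PrimerSpec-class}}.
#' @param params a \code{\link{FilterParams-class}}.
#' @param minFold bimera parent-overabundance threshold (default 3.5).
#' @param sampleName sample identifier for the output table.
#' @param ... passed to \code{\link{learnErrors}} / \code{\link{runDada}}
#'   (e.g. \code{omegaA}, \code{band}, \code{maxRounds}).
#' @param verbose print stage progress.
#' @return list with \code{reads} (filtered), \code{tally}, \code{model},
#'   \code{diagnostics}, \code{dada} (\code{\link{DadaResult-class}}),
#'   \code{table} (chimera-free \code{\link{AsvTable-class}}) and
#'   \code{flagged} (bimera report).
#' @export
denoisePipeline <- function(reads, primers = primerSpec(),
                            params = filterParams(), minFold = 3.5,
                            sampleName = "sample1", ..., verbose = FALSE) {
  if (is.character(reads)) reads <- readAmpliconFastq(reads)
  prep <- prepareReads(reads, primers, params)
  if (verbose)
    message(sprintf("filtered: %d of %d reads kept", prep$tally[["kept"]],
                    prep$tally[["input"]]))
  drp <- dereplicate(prep$reads)
  dots <- list(...)
  le_args <- dots[names(dots) %in% c("maxRounds", "tol", "initModel",
                                     names(formals(runDada)))]
  rd_args <- dots[names(dots) %in% names(formals(runDada))]
  le <- do.call(learnErrors, c(list(drp), le_args, list(verbose = verbose)))
  dd <- do.call(runDada, c(list(drp, le$model), rd_args))
  if (verbose) message(sprintf("denoised: %d sequence variants", nrow(dd@asv)))
  tab <- makeAsvTable(dd, sampleName)
  rb <- removeBimeras(tab, minFold = minFold)
  if (verbose)
    message(sprintf("chimera removal: %d of %d ASVs removed",
                    sum(rb$flagged$removed), ncol(tab@table)))
  list(reads = prep$reads, tally = prep$tally, model = le$model,
       diagnostics = le$diagnostics, dada = dd, table = rb$table,
       flagged = rb$flagged)
}
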