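## Accessors and show() methods.

#' @describeIn GenomeInfo-class chromosome sizes
#' @param x object
#' @export
setMethod("chromSizes", "GenomeInfo", function(x) x@chromSizes)
#' @describeIn GenomeInfo-class effective genome size (bp)
#' @export
setMethod("effectiveGenomeSize", "GenomeInfo", function(x) x@effectiveGenomeSize)
#' @describeIn GenomeInfo-class FASTA path (or NA)
#' @export
setMethod("fastaPath", "GenomeInfo", function(x) x@fastaPath)

setMethod("show", "GenomeInfo", function(object) {
    cat("GenomeInfo:", length(object@chromSizes), "chromosome(s),",
        format(sum(object@chromSizes), big.mark = ","), "bp total;",
        "effective", format(object@effectiveGenomeSize, big.mark = ","), "bp\n")
    if (!is.na(object@fastaPath))
        cat("  FASTA:", object@fastaPath, "\n")
})

#' @describeIn SampleMeta-class sample identifier
#' @param x object
#' @export
setMethod("sampleId", "SampleMeta", function(x) x@sampleId)
#' @describeIn SampleMeta-class MNase concentration (U)
#' @export
setMethod("concentration", "SampleMeta", function(x) x@concentration)
#' @describeIn SampleMeta-class replicate label
#' @export
setMethod("replicateLabel", "SampleMeta", function(x) x@replicateLabel)
#' @describeIn SampleMeta-class spike-in fragment count (or NA)
#' @export
setMethod("spikeInFragments", "SampleMeta", function(x) x@spikeInFragments)

setMethod("show", "SampleMeta", function(object) {
    cat(sprintf("SampleMeta '%s': %g U, %s%s\n", object@sampleId,
                object@concentration, object@replicateLabel,
                if (is.na(object@spikeInFragments)) "" else
                    sprintf(", spike-in %g fragments", object@spikeInFragments)))
})

#' @describeIn FragmentSet-class fragment intervals as GRanges
#' @param x object
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)
#' @describeIn FragmentSet-class size fraction label
#' @export
setMethod("fraction", "FragmentSet", function(x) x@fraction)
#' @describeIn FragmentSet-class number of fragments
#' @export
setMethod("nFragments", "FragmentSet", function(x) length(x@fragments))
#' @describeIn FragmentSet-class originating sample metadata
#' @export
setMethod("sampleId", "FragmentSet", function(x) x@sample@sampleId)
#' @describeIn FragmentSet-class MNase concentration of the sample
#' @export
setMethod("concentration", "FragmentSet", function(x) x@sample@concentration)

#' Sample metadata of a FragmentSet
#' @param x a \code{FragmentSet}
#' @return the embedded \code{SampleMeta}
#' @export
sampleMeta <- function(x) {
    stopifnot(is(x, "FragmentSet"))
    x@sample
}

setMethod("show", "FragmentSet", function(object) {
    cat(sprintf("FragmentSet '%s' (%s): %d fragments\n",
                object@sample@sampleId, object@fraction,
                length(object@fragments)))
})

#' @describeIn PositionSet-class position intervals as GRanges
#' @param x object
#' @export
setMethod("positions", "PositionSet", function(x) x@positions)
#' @describeIn PositionSet-class position kind ("mono"/"sub")
#' @export
setMethod("kind", "PositionSet", function(x) x@kind)
#' @describeIn PositionSet-class summit coordinates (1-based)
#' @export
setMethod("summits", "PositionSet", function(x) S4Vectors::mcols(x@positions)$summit)
#' @describeIn PositionSet-class normalized pileup height at summit
#' @export
setMethod("occupancy", "PositionSet", function(x) S4Vectors::mcols(x@positions)$occupancy)
#' @describeIn PositionSet-class number of positions
#' @export
setMethod("length", "PositionSet", function(x) length(x@positions))

setMethod("show", "PositionSet", function(object) {
    cat(sprintf("PositionSet (%s): %d positions\n", object@kind,
                length(object@positions)))
})

#' Subset a PositionSet
#' @param x a \code{PositionSet}
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "PositionSet", function(x, i, j, ..., drop = TRUE) {
    PositionSet(x@positions[i], x@kind)
})

#' @describeIn NucCountMatrix-class position kind
#' @param x object
#' @export
setMethod("kind", "NucCountMatrix", function(x) x@kind)
#' @describeIn NucCountMatrix-class normalization state
#' @export
setMethod("normState", "NucCountMatrix", function(x) x@normState)
#' @describeIn NucCountMatrix-class stored pseudocount (NA until set)
#' @export
setMethod("pseudocount", "NucCountMatrix", function(x) x@pseudocount)
#' @describeIn NucCountMatrix-class MNase concentrations of the samples
#' @export
setMethod("concentration", "NucCountMatrix",
          function(x) SummarizedExperiment::colData(x)$concentration)

setMethod("show", "NucCountMatrix", function(object) {
    cat(sprintf("NucCountMatrix (%s, %s): %d positions x %d samples\n",
                object@kind, object@normState, nrow(object), ncol(object)))
    callNextMethod()
})

#' @describeIn ScoreTable-class annotated position GRanges
#' @param x object
#' @export
setMethod("positions", "ScoreTable", function(x) x@positions)
#' @describeIn ScoreTable-class score kind
#' @export
setMethod("kind", "ScoreTable", function(x) x@kind)
#' @describeIn ScoreTable-class GC-corrected scores
#' @export
setMethod("scores", "ScoreTable", function(x) S4Vectors::mcols(x@positions)$score)
#' @describeIn ScoreTable-class raw (uncorrected) regression scores
#' @export
setMethod("rawScores", "ScoreTable", function(x) S4Vectors::mcols(x@positions)$rawScore)
#' @describeIn ScoreTable-class per-position GC fraction
#' @export
setMethod("gcFraction", "ScoreTable", function(x) S4Vectors::mcols(x@positions)$gc)
#' @describeIn ScoreTable-class classification labels
#' @export
setMethod("classLabels", "ScoreTable", function(x) S4Vectors::mcols(x@positions)$label)
#' @describeIn ScoreTable-class number of scored positions
#' @export
setMethod("length", "ScoreTable", function(x) length(x@positions))

#' Subset a ScoreTable
#' @param x a \code{ScoreTable}
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "ScoreTable", function(x, i, j, ..., drop = TRUE) {
    ScoreTable(x@positions[i], x@kind)
})

setMethod("show", "ScoreTable", function(object) {
    lab <- S4Vectors::mcols(object@positions)$label
    scoreName <- if (object@kind == "mono") "nucMACC" else "sub-nucMACC"
    cat(sprintf("ScoreTable (%s, %s): %d positions\n", object@kind, scoreName,
                length(object@positions)))
    if (any(!is.na(lab))) {
        tab <- table(lab)
        cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
})

#' @describeIn CutoffResult-class indices of the low-score tail
#' @param x object
#' @export
setMethod("lowSet", "CutoffResult", function(x) x@lowSet)
#' @describeIn CutoffResult-class indices of the high-score tail
#' @export
setMethod("highSet", "CutoffResult", function(x) x@highSet)
#' @describeIn CutoffResult-class rank-curve diagnostic table
#' @export
setMethod("cutoffCurve", "CutoffResult", function(x) x@curve)

setMethod("show", "CutoffResult", function(object) {
    cat(sprintf("CutoffResult: low tail n=%d (rank %.4g), high tail n=%d (rank %.4g)\n",
                length(object@lowSet), object@lowCutoffRank,
                length(object@highSet), object@highCutoffRank))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d nucleosomes on %d chromosome(s); ",
                       "%d x %d samples (c = %s U); depth %g; seed %d\n"),
                object@nNucleosomes, object@nChromosomes,
                length(object@concentrations), object@replicates,
                paste(object@concentrations, collapse = "/"),
                object@depth, object@seed))
})
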