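#' Accessors for GlandCohort slots
#'
#' Standard accessor generics for the cohort container; use these rather than
#' direct slot access.
#'
#' @param x A [GlandCohort-class] object.
#' @param ... ignored.
#' @return The corresponding table, matrix or \code{GRanges}.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cohortPatients", function(x, ...) standardGeneric("cohortPatients"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortSamples", function(x, ...) standardGeneric("cohortSamples"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortMutations", function(x, ...) standardGeneric("cohortMutations"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortGenotypes", function(x, ...) standardGeneric("cohortGenotypes"))
#' @rdname cohort-accessors
#' @export
setGeneric("rnaSupport", function(x, ...) standardGeneric("rnaSupport"))
#' @rdname cohort-accessors
#' @export
setGeneric("hlaStates", function(x, ...) standardGeneric("hlaStates"))
#' @rdname cohort-accessors
#' @param scale \code{"vst"} or \code{"tpm"}.
#' @export
setGeneric("expressionMatrix",
           function(x, scale = c("vst", "tpm"), ...)
             standardGeneric("expressionMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("atacFoldChange", function(x, ...) standardGeneric("atacFoldChange"))
#' @rdname cohort-accessors
#' @export
setGeneric("atacPeaks", function(x, ...) standardGeneric("atacPeaks"))
#' @rdname cohort-accessors
#' @export
setGeneric("promoterRegions", function(x, ...) standardGeneric("promoterRegions"))
#' @rdname cohort-accessors
#' @export
setGeneric("tfBindingSites", function(x, ...) standardGeneric("tfBindingSites"))
#' @rdname cohort-accessors
#' @export
setGeneric("immunopeptidomeRegions",
           function(x, ...) standardGeneric("immunopeptidomeRegions"))

#' @rdname cohort-accessors
#' @export
setMethod("cohortPatients", "GlandCohort", function(x, ...) x@patients)
#' @rdname cohort-accessors
#' @export
setMethod("cohortSamples", "GlandCohort", function(x, ...) x@samples)
#' @rdname cohort-accessors
#' @export
setMethod("cohortMutations", "GlandCohort", function(x, ...) x@mutations)
#' @rdname cohort-accessors
#' @export
setMethod("cohortGenotypes", "GlandCohort", function(x, ...) x@genotypes)
#' @rdname cohort-accessors
#' @export
setMethod("rnaSupport", "GlandCohort", function(x, ...) x@rnaSupport)
#' @rdname cohort-accessors
#' @export
setMethod("hlaStates", "GlandCohort", function(x, ...) x@hlaStates)
#' @rdname cohort-accessors
#' @export
setMethod("expressionMatrix", "GlandCohort",
          function(x, scale = c("vst", "tpm"), ...) {
            scale <- match.arg(scale)
            if (scale == "vst") x@vst else x@tpm
          })
#' @rdname cohort-accessors
#' @export
setMethod("atacFoldChange", "GlandCohort", function(x, ...) x@atacFC)
#' @rdname cohort-accessors
#' @export
setMethod("atacPeaks", "GlandCohort", function(x, ...) x@peaks)
#' @rdname cohort-accessors
#' @export
setMethod("promoterRegions", "GlandCohort", function(x, ...) x@promoters)
#' @rdname cohort-accessors
#' @export
setMethod("tfBindingSites", "GlandCohort", function(x, ...) x@tfSites)
#' @rdname cohort-accessors
#' @export
setMethod("immunopeptidomeRegions", "GlandCohort", function(x, ...) x@onRegions)

#' Does the cohort carry RNA variant support?
#'
#' @param x A [GlandCohort-class].
#' @return Logical scalar.
#' @export
hasRnaSupport <- function(x) .hasTable(x@rnaSupport)

#' Does the cohort carry an ATAC fold-change matrix?
#'
#' @param x A [GlandCohort-class].
#' @return Logical scalar.
#' @export
hasAtac <- function(x) .hasMatrix(x@atacFC)
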