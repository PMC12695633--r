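## Transcriptional immuno-editing: expressed/edited classification from RNA
## allele counts and cohort-level editing statistics.

#' Classify per-mutation-per-sample expression status
#'
#' A mutation is \code{expressed} in a sample when three or more RNA reads
#' support the variant base; \code{edited} (confidently not expressed) when
#' more than ten reads overlap the position with zero supporting the
#' variant; otherwise \code{insufficient}. The depth cut of "more than ten"
#' keeps the probability of misclassifying a variant at true allele
#' frequency >= 0.25 below 5\% (see [minDepthForMisclassification()]).
#'
#' @param ref_reads,alt_reads Non-negative integer vectors of RNA read
#'   counts.
#' @param min_alt Expressed threshold (default 3).
#' @param min_depth Edited requires depth strictly greater than this
#'   (default 10).
#' @return Character vector: \code{"expressed"}, \code{"edited"},
#'   \code{"insufficient"}.
#' @export
classifyExpression <- function(ref_reads, alt_reads, min_alt = 3,
                               min_depth = 10) {
  stopifnot(all(ref_reads >= 0), all(alt_reads >= 0))
  depth <- ref_reads + alt_reads
  ifelse(alt_reads >= min_alt, "expressed",
         ifelse(depth > min_depth & alt_reads == 0, "edited",
                "insufficient"))
}

#' Minimum depth bounding the misclassification probability
#'
#' Smallest integer depth d such that a variant truly present at allele
#' frequency \code{af} yields zero supporting reads with probability
#' (1-af)^d below \code{alpha}.
#'
#' @param af True allele frequency in (0, 1].
#' @param alpha Misclassification bound in (0, 1).
#' @return list with \code{depth} and \code{probability} = (1-af)^depth.
#' @examples
#' minDepthForMisclassification(0.25, 0.05)  # depth 11, ~4.2%
#' @export
minDepthForMisclassification <- function(af, alpha) {
  if (af <= 0) stop("af must be positive (af = 0 is unbounded)")
  if (af > 1 || alpha <= 0 || alpha >= 1) stop("invalid af or alpha")
  if (af == 1) return(list(depth = 1L, probability = 0))
  d <- max(1L, as.integer(ceiling(log(alpha) / log(1 - af))))
  while ((1 - af)^d >= alpha) d <- d + 1L          # guard against rounding
  while (d > 1L && (1 - af)^(d - 1L) < alpha) d <- d - 1L
  list(depth = d, probability = (1 - af)^d)
}

#' Expression calls for all DNA-present mutation-sample pairs
#'
#' Evaluates [classifyExpression()] only where the mutation is present in
#' DNA in that sample.
#'
#' @param cohort A [GlandCohort-class] with RNA support.
#' @return data.frame with \code{mutation_id}, \code{sample_id},
#'   \code{status}.
#' @export
expressionCalls <- function(cohort) {
  if (!hasRnaSupport(cohort)) {
    warning("cohort carries no RNA support; editing stages are empty")
    return(data.frame(mutation_id = character(0), sample_id = character(0),
                      status = character(0)))
  }
  rs <- rnaSupport(cohort)
  gt <- cohortGenotypes(cohort)
  key <- paste(rs$mutation_id, rs$sample_id)
  dna <- paste(gt$mutation_id[gt$present], gt$sample_id[gt$present])
  rs <- rs[key %in% dna, ]
  data.frame(mutation_id = rs$mutation_id, sample_id = rs$sample_id,
             status = classifyExpression(rs$ref_reads, rs$alt_reads),
             stringsAsFactors = FALSE)
}

## Mutation-level editing table: evaluable sample count, edited-anywhere
## flag and editing breadth; only SNV-class consequences enter by default
## (RNA counting targets substitutions).
.editingTable <- function(cohort, calls, clonality = NULL,
                          min_samples = 2, snv_only = TRUE) {
  mu <- cohortMutations(cohort)
  if (snv_only) mu <- mu[mu$consequence != "frameshift", ]
  calls <- calls[calls$mutation_id %in% mu$mutation_id, ]
  ev <- calls[calls$status != "insufficient", ]
  nEval <- table(factor(ev$mutation_id, levels = mu$mutation_id))
  nEd <- table(factor(ev$mutation_id[ev$status == "edited"],
                      levels = mu$mutation_id))
  out <- data.frame(
    mutation_id = mu$mutation_id, patient_id = mu$patient_id,
    neoantigen = .isNeoantigen(mu$strong_binder_count),
    n_evaluable = as.integer(nEval[mu$mutation_id]),
    n_edited = as.integer(nEd[mu$mutation_id]), stringsAsFactors = FALSE)
  out$edited_any <- out$n_edited >= 1
  out$breadth <- ifelse(out$n_evaluable > 0,
                        out$n_edited / out$n_evaluable, NA_real_)
  if (!is.null(clonality))
    out$clonality <- clonality$label[match(out$mutation_id,
                                           clonality$mutation_id)]
  out[out$n_evaluable >= min_samples, ]
}

#' Per-cancer transcriptional editing summary
#'
#' Per cancer: the proportion of mutations edited in at least one sample,
#' split by neoantigen status (and clonality stratum when calls are
#' supplied); per mutation: the fraction of evaluable samples in which it
#' is edited. Mutations with confident expressed/edited status in fewer
#' than \code{min_samples} samples are excluded. Neoantigen vs
#' nonantigenic per-cancer proportions are compared by a two-sided paired
#' Wilcoxon signed-rank test.
#'
#' @param cohort A [GlandCohort-class].
#' @param calls Optional precomputed [expressionCalls()].
#' @param clonality Optional [classifyClonality()] output.
#' @param min_samples Minimum evaluable samples per mutation (default 2).
#' @return list with \code{per_cancer}, \code{per_mutation},
#'   \code{p_value} (paired Wilcoxon; NA with < 3 informative cancers).
#' @export
editingSummary <- function(cohort, calls = NULL, clonality = NULL,
                           min_samples = 2) {
  if (is.null(calls)) calls <- expressionCalls(cohort)
  if (!nrow(calls)) {
    warning("no RNA expression calls available; empty editing summary")
    return(list(per_cancer = data.frame(), per_mutation = data.frame(),
                p_value = NA_real_))
  }
  et <- .editingTable(cohort, calls, clonality, min_samples)
  per <- lapply(split(et, et$patient_id), function(d) {
    data.frame(cancer_id = d$patient_id[1],
               n_mutations = nrow(d),
               prop_edited_neoantigen = if (any(d$neoantigen))
                 mean(d$edited_any[d$neoantigen]) else NA_real_,
               prop_edited_nonantigenic = if (any(!d$neoantigen))
                 mean(d$edited_any[!d$neoantigen]) else NA_real_,
               median_breadth_neoantigen = if (any(d$neoantigen))
                 stats::median(d$breadth[d$neoantigen]) else NA_real_,
               median_breadth_nonantigenic = if (any(!d$neoantigen))
                 stats::median(d$breadth[!d$neoantigen]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ok <- stats::complete.cases(per[, c("prop_edited_neoantigen",
                                      "prop_edited_nonantigenic")])
  p <- if (sum(ok) >= 3)
    .pairedWilcoxon(per$prop_edited_neoantigen[ok],
                    per$prop_edited_nonantigenic[ok]) else NA_real_
  list(per_cancer = per, per_mutation = et, p_value = p)
}

#' Odds ratio of transcriptional editing for neoantigens
#'
#' 2x2 association (neoantigen vs nonantigenic x edited in >= 1 sample vs
#' never) over mutations with at least \code{min_samples} evaluable
#' samples, via the exact conditional odds-ratio engine. Supports
#' clonality strata and exclusion of individual cancers (mirroring
#' leave-one-cancer-out checks on hypermutant outliers).
#'
#' @param cohort A [GlandCohort-class].
#' @param calls Optional precomputed [expressionCalls()].
#' @param stratum \code{"all"}, \code{"clonal"} or \code{"subclonal"}.
#' @param clonality [classifyClonality()] output (required for strata).
#' @param exclude_cancers Character vector of patient ids to drop.
#' @param min_samples Minimum evaluable samples per mutation.
#' @return list with \code{table} and [exactOddsRatio()] fields.
#' @export
editingOddsRatio <- function(cohort, calls = NULL,
                             stratum = c("all", "clonal", "subclonal"),
                             clonality = NULL, exclude_cancers = character(0),
                             min_samples = 2) {
  stratum <- match.arg(stratum)
  if (is.null(calls)) calls <- expressionCalls(cohort)
  et <- .editingTable(cohort, calls, clonality, min_samples)
  if (stratum != "all") {
    if (is.null(clonality)) stop("clonality calls required for strata")
    et <- et[!is.na(et$clonality) & et$clonality == stratum, ]
  }
  et <- et[!et$patient_id %in% exclude_cancers, ]
  tab <- matrix(c(sum(et$neoantigen & et$edited_any),
                  sum(et$neoantigen & !et$edited_any),
                  sum(!et$neoantigen & et$edited_any),
                  sum(!et$neoantigen & !et$edited_any)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("neoantigen", "nonantigenic"),
                                c("edited", "never_edited")))
  c(list(table = tab, n_mutations = nrow(et)), exactOddsRatio(tab))
}

#' Downsampled clonal editing significance check
#'
#' Repeatedly subsamples the clonal mutations to the subclonal count and
#' recomputes the editing odds-ratio significance, returning how many
#' replicates reach two-sided exact p < \code{alpha}. Used to check
#' whether a clonal-only signal survives at subclonal sample size.
#'
#' @param cohort A [GlandCohort-class].
#' @param clonality [classifyClonality()] output.
#' @param target Number of clonal mutations to keep per replicate
#'   (default: the cohort's subclonal mutation count).
#' @param reps Number of replicates (default 50).
#' @param alpha Significance threshold (default 0.05).
#' @param calls Optional precomputed [expressionCalls()].
#' @param seed Optional seed.
#' @return list with \code{n_significant}, \code{reps}, \code{p_values}.
#' @export
downsampleClonalTest <- function(cohort, clonality, target = NULL,
                                 reps = 50, alpha = 0.05, calls = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(calls)) calls <- expressionCalls(cohort)
  et <- .editingTable(cohort, calls, clonality, min_samples = 2)
  clonalIds <- et$mutation_id[!is.na(et$clonality) &
                                et$clonality == "clonal"]
  if (is.null(target))
    target <- sum(!is.na(et$clonality) & et$clonality == "subclonal")
  if (target > length(clonalIds))
    stop("target exceeds the number of clonal mutations", call. = FALSE)
  ps <- vapply(seq_len(reps), function(r) {
    keep <- sample(clonalIds, target)
    d <- et[et$mutation_id %in% keep, ]
    tab <- matrix(c(sum(d$neoantigen & d$edited_any),
                    sum(d$neoantigen & !d$edited_any),
                    sum(!d$neoantigen & d$edited_any),
                    sum(!d$neoantigen & !d$edited_any)), 2, byrow = TRUE)
    exactOddsRatio(tab)$p_value
  }, numeric(1))
  list(n_significant = sum(ps < alpha), reps = reps, p_values = ps)
}
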