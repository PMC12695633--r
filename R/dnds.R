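## Opportunity-normalised dN/dS inside vs outside the immunopeptidome.
## The immune dN/dS statistic is the ratio of ON-target to OFF-target
## dN/dS, which cancels technical artefacts (context-spectrum
## mis-specification, global rate scaling) shared by the two region
## classes.

#' Synthetic coding model for the simulated genome
#'
#' Per-context counts of synonymous and nonsynonymous sites inside (ON)
#' and outside (OFF) the immunopeptidome, matching the generator's
#' geometry: a 1:3 synonymous:nonsynonymous site ratio in both region
#' classes, with the ON class covering \code{on_fraction} of the coding
#' space.
#'
#' @param on_fraction Fraction of coding space in the ON class.
#' @return data.frame with \code{region_class}, \code{context},
#'   \code{syn_sites}, \code{nonsyn_sites} (384 rows).
#' @export
syntheticCodingModel <- function(on_fraction = 0.15) {
  ctx <- trinucContexts()
  rbind(
    data.frame(region_class = "ON", context = ctx,
               syn_sites = 0.25 * on_fraction,
               nonsyn_sites = 0.75 * on_fraction),
    data.frame(region_class = "OFF", context = ctx,
               syn_sites = 0.25 * (1 - on_fraction),
               nonsyn_sites = 0.75 * (1 - on_fraction)))
}

#' Build spectrum-weighted mutation opportunities
#'
#' Weights the per-context synonymous/nonsynonymous site counts of a
#' coding model by a 192-context relative mutation-rate spectrum, yielding
#' the expected opportunity totals per region class. Doubling the spectrum
#' leaves downstream dN/dS ratios unchanged (scale invariance).
#'
#' @param coding_model data.frame as returned by [syntheticCodingModel()].
#' @param spectrum Named numeric vector of relative rates over the 192
#'   contexts (default uniform). Every context present in the coding model
#'   must be covered.
#' @return data.frame with \code{region_class}, \code{opp_syn},
#'   \code{opp_nonsyn}.
#' @export
buildOpportunities <- function(coding_model, spectrum = NULL) {
  if (is.null(spectrum)) {
    spectrum <- stats::setNames(rep(1, 192), trinucContexts())
  }
  miss <- setdiff(unique(coding_model$context), names(spectrum))
  if (length(miss))
    stop("context absent from spectrum: ", miss[1], call. = FALSE)
  w <- spectrum[coding_model$context]
  agg <- function(v) tapply(v * w, coding_model$region_class, sum)
  s <- agg(coding_model$syn_sites); n <- agg(coding_model$nonsyn_sites)
  data.frame(region_class = names(s), opp_syn = as.numeric(s),
             opp_nonsyn = as.numeric(n[names(s)]), stringsAsFactors = FALSE)
}

#' Opportunity-normalised dN/dS
#'
#' (observed nonsynonymous / nonsynonymous opportunity) divided by
#' (observed synonymous / synonymous opportunity). A zero synonymous count
#' flags the estimate ineligible rather than erroring.
#'
#' @param n_nonsyn,n_syn Observed mutation counts.
#' @param opp_nonsyn,opp_syn Opportunities (> 0).
#' @return list with \code{dnds} and \code{eligible}.
#' @export
computeDnds <- function(n_nonsyn, n_syn, opp_nonsyn, opp_syn) {
  stopifnot(opp_nonsyn > 0, opp_syn > 0)
  if (n_syn == 0) return(list(dnds = NA_real_, eligible = FALSE))
  list(dnds = (n_nonsyn / opp_nonsyn) / (n_syn / opp_syn), eligible = TRUE)
}

#' Immune dN/dS from a mutation set
#'
#' Computes ON- and OFF-target dN/dS and their ratio (immune dN/dS) from a
#' mutation table annotated with consequence and ON-target membership.
#' Frameshifts and non-coding consequences are excluded; synonymous counts
#' of zero in either class mark the sample ineligible (as samples without
#' ON- or OFF-target synonymous mutations are excluded from the analysis).
#' The CI is a normal approximation on the log ratio with variance equal
#' to the sum of reciprocal counts.
#'
#' @param consequence Character vector (synonymous/missense/nonsense/
#'   splice/frameshift/other).
#' @param on_target Logical vector, parallel.
#' @param opportunities Output of [buildOpportunities()] with rows
#'   \code{ON} and \code{OFF}.
#' @param conf_level CI level (default 0.95).
#' @return list: counts (\code{n_nonsyn_on}, \code{n_syn_on},
#'   \code{n_nonsyn_off}, \code{n_syn_off}), \code{dnds_on},
#'   \code{dnds_off}, \code{immune_dnds}, \code{ci_low}, \code{ci_high},
#'   \code{eligible}.
#' @export
immuneDnds <- function(consequence, on_target,
                       opportunities = buildOpportunities(
                         syntheticCodingModel()),
                       conf_level = 0.95) {
  snv_non <- consequence %in% c("missense", "nonsense", "splice")
  snv_syn <- consequence == "synonymous"
  opp <- opportunities
  oON <- opp[opp$region_class == "ON", ]
  oOFF <- opp[opp$region_class == "OFF", ]
  cnt <- list(n_nonsyn_on = sum(snv_non & on_target),
              n_syn_on = sum(snv_syn & on_target),
              n_nonsyn_off = sum(snv_non & !on_target),
              n_syn_off = sum(snv_syn & !on_target))
  dOn <- computeDnds(cnt$n_nonsyn_on, cnt$n_syn_on, oON$opp_nonsyn,
                     oON$opp_syn)
  dOff <- computeDnds(cnt$n_nonsyn_off, cnt$n_syn_off, oOFF$opp_nonsyn,
                      oOFF$opp_syn)
  eligible <- dOn$eligible && dOff$eligible && cnt$n_nonsyn_on > 0 &&
    cnt$n_nonsyn_off > 0
  res <- c(cnt, list(dnds_on = dOn$dnds, dnds_off = dOff$dnds,
                     immune_dnds = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, eligible = eligible))
  if (!eligible) return(res)
  res$immune_dnds <- dOn$dnds / dOff$dnds
  v <- sum(1 / unlist(cnt))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res$ci_low <- exp(log(res$immune_dnds) - z * sqrt(v))
  res$ci_high <- exp(log(res$immune_dnds) + z * sqrt(v))
  res
}

#' Per-sample immune dN/dS across a cohort
#'
#' ON-target membership is derived by overlapping mutation positions with
#' the cohort's immunopeptidome regions. Clonal-only analysis reuses the
#' same machinery after filtering to clonal mutations.
#'
#' @param cohort A [GlandCohort-class] with immunopeptidome regions.
#' @param opportunities Output of [buildOpportunities()].
#' @param clonality Optional [classifyClonality()] output.
#' @param stratum \code{"all"} or \code{"clonal"}.
#' @return data.frame, one row per deep carcinoma sample, with the
#'   [immuneDnds()] fields; ineligible samples carry \code{NA} estimates.
#' @export
immuneDndsPerSample <- function(cohort,
                                opportunities = buildOpportunities(
                                  syntheticCodingModel()),
                                clonality = NULL,
                                stratum = c("all", "clonal")) {
  stratum <- match.arg(stratum)
  on <- immunopeptidomeRegions(cohort)
  if (is.null(on)) stop("cohort carries no immunopeptidome regions")
  mu <- cohortMutations(cohort)
  if (stratum == "clonal") {
    if (is.null(clonality)) stop("clonal stratum needs clonality calls")
    lab <- clonality$label[match(mu$mutation_id, clonality$mutation_id)]
    mu <- mu[!is.na(lab) & lab == "clonal", ]
  }
  mgr <- GenomicRanges::GRanges(mu$chrom, IRanges::IRanges(mu$pos, mu$pos))
  mu$on_target <- IRanges::overlapsAny(mgr, on)
  gt <- cohortGenotypes(cohort)
  gt <- gt[gt$present & gt$mutation_id %in% mu$mutation_id, ]
  sm <- cohortSamples(cohort)
  deep <- sm$sample_id[sm$tissue == "carcinoma" & sm$assay == "wgs_deep"]
  rows <- lapply(deep, function(s) {
    ids <- gt$mutation_id[gt$sample_id == s]
    m <- mu[mu$mutation_id %in% ids, ]
    r <- immuneDnds(m$consequence, m$on_target, opportunities)
    data.frame(sample_id = s, as.data.frame(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$patient_id <- sm$patient_id[match(out$sample_id, sm$sample_id)]
  rownames(out) <- NULL
  out
}
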