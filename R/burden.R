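## Clonality assignment and proportional neoantigen burden.

#' Clonality rule for a single mutation
#'
#' Applies the multi-region presence rule: in \code{wgs} mode a mutation
#' present in every eligible deep-sequenced cancer biopsy is clonal and any
#' other mutation is subclonal; in \code{panel} mode a mutation present in
#' all biopsies is clonal, absent in at least two is subclonal, and absent
#' in exactly one is unclassified.
#'
#' @param n_present Number of eligible biopsies carrying the mutation.
#' @param n_eligible Number of eligible biopsies (must be >= 2).
#' @param mode \code{"wgs"} or \code{"panel"}.
#' @return \code{"clonal"}, \code{"subclonal"} or \code{"unclassified"}.
#' @export
clonalityRule <- function(n_present, n_eligible, mode = c("wgs", "panel")) {
  mode <- match.arg(mode)
  if (any(n_eligible < 2))
    stop("not evaluable: clonality needs at least 2 eligible samples",
         call. = FALSE)
  absent <- n_eligible - n_present
  if (mode == "wgs") {
    ifelse(absent == 0, "clonal", "subclonal")
  } else {
    ifelse(absent == 0, "clonal",
           ifelse(absent >= 2, "subclonal", "unclassified"))
  }
}

#' Classify clonality of every mutation in a cohort
#'
#' Eligible samples are deep-sequenced carcinoma biopsies (low-pass and
#' normal samples never count). Mutations of a patient with no genotype row
#' in any eligible sample (e.g. adenoma-private mutations) are returned as
#' \code{NA}.
#'
#' @param cohort A [GlandCohort-class].
#' @param mode \code{"wgs"} (default) or \code{"panel"}; the panel rule
#'   leaves single-absence mutations unclassified.
#' @return data.frame with \code{mutation_id}, \code{patient_id},
#'   \code{label}, \code{mode}.
#' @export
classifyClonality <- function(cohort, mode = c("wgs", "panel")) {
  mode <- match.arg(mode)
  sm <- cohortSamples(cohort)
  elig <- sm$sample_id[sm$tissue == "carcinoma" & sm$assay == "wgs_deep"]
  nElig <- table(sm$patient_id[sm$sample_id %in% elig])
  mu <- cohortMutations(cohort)
  if (any(nElig[unique(mu$patient_id)] < 2, na.rm = TRUE) ||
      any(!unique(mu$patient_id) %in% names(nElig)))
    stop("not evaluable: every patient needs >= 2 eligible cancer samples",
         call. = FALSE)
  gt <- cohortGenotypes(cohort)
  gt <- gt[gt$present & gt$sample_id %in% elig, ]
  gt <- unique(gt[, c("mutation_id", "sample_id")])
  np <- table(factor(gt$mutation_id, levels = mu$mutation_id))
  nPresent <- as.integer(np[mu$mutation_id])
  nE <- as.integer(nElig[mu$patient_id])
  label <- rep(NA_character_, nrow(mu))
  has <- nPresent > 0
  label[has] <- clonalityRule(nPresent[has], nE[has], mode)
  data.frame(mutation_id = mu$mutation_id, patient_id = mu$patient_id,
             label = label, mode = mode, stringsAsFactors = FALSE)
}

.strataFilter <- function(mu, stratum, clonality = NULL) {
  keep <- rep(TRUE, nrow(mu))
  if (stratum %in% c("clonal", "subclonal")) {
    if (is.null(clonality))
      stop("clonal/subclonal strata need clonality calls")
    lab <- clonality$label[match(mu$mutation_id, clonality$mutation_id)]
    keep <- keep & !is.na(lab) & lab == stratum
  }
  if (stratum == "snv_only") keep <- keep & mu$consequence != "frameshift"
  if (stratum == "frameshift_only")
    keep <- keep & mu$consequence == "frameshift"
  keep
}

#' Proportional neoantigen burden per sample
#'
#' For every tumour sample, the number of present mutations with at least
#' one strong-binding peptide divided by the number of present
#' protein-changing mutations, within the requested stratum. The SNV-only
#' stratum excludes frameshifts from numerator and denominator alike. A
#' zero denominator yields an absent (\code{NA}) burden with a warning,
#' never 0.
#'
#' @param cohort A [GlandCohort-class].
#' @param stratum One of \code{"all"}, \code{"clonal"}, \code{"subclonal"},
#'   \code{"snv_only"}, \code{"frameshift_only"}.
#' @param clonality Optional output of [classifyClonality()]; required for
#'   the clonal/subclonal strata.
#' @return data.frame with \code{sample_id}, \code{patient_id},
#'   \code{tissue}, \code{n_neoantigen}, \code{n_protein_changing},
#'   \code{proportional_burden}, \code{stratum}.
#' @export
proportionalBurden <- function(cohort,
                               stratum = c("all", "clonal", "subclonal",
                                           "snv_only", "frameshift_only"),
                               clonality = NULL) {
  stratum <- match.arg(stratum)
  mu <- cohortMutations(cohort)
  sm <- cohortSamples(cohort)
  gt <- cohortGenotypes(cohort)
  keep <- .strataFilter(mu, stratum, clonality)
  mu <- mu[keep & .proteinChanging(mu$consequence), ]
  gt <- gt[gt$present & gt$mutation_id %in% mu$mutation_id, ]
  gt <- unique(gt[, c("mutation_id", "sample_id")])  # duplicate-row safe
  neo <- .isNeoantigen(mu$strong_binder_count)
  gt$neo <- neo[match(gt$mutation_id, mu$mutation_id)]
  tum <- sm[sm$tissue != "normal", ]
  npc <- table(factor(gt$sample_id, levels = tum$sample_id))
  nneo <- table(factor(gt$sample_id[gt$neo], levels = tum$sample_id))
  n_pc <- as.integer(npc[tum$sample_id])
  n_neo <- as.integer(nneo[tum$sample_id])
  pb <- ifelse(n_pc > 0, n_neo / n_pc, NA_real_)
  if (any(n_pc == 0))
    warning(sprintf("%d sample(s) without protein-changing mutations in stratum '%s'; burden reported as absent",
                    sum(n_pc == 0), stratum), call. = FALSE)
  data.frame(sample_id = tum$sample_id, patient_id = tum$patient_id,
             tissue = tum$tissue, n_neoantigen = n_neo,
             n_protein_changing = n_pc, proportional_burden = pb,
             stratum = stratum, stringsAsFactors = FALSE)
}

#' Adenoma vs carcinoma burden comparison
#'
#' Tests whether proportional neoantigen burden differs between adenoma
#' (CRA) and carcinoma (CRC) biopsies, with Patient as a random intercept:
#' a likelihood-ratio comparison of mixed models with and without the
#' tissue fixed effect (see [patientRandomEffectTest()]).
#'
#' @param burden Output of [proportionalBurden()] covering adenoma and
#'   carcinoma samples.
#' @return list with \code{p_value}, \code{estimate} (carcinoma effect on
#'   the burden scale), \code{direction} and the underlying table.
#' @export
craVsCrcBurdenTest <- function(burden) {
  b <- burden[!is.na(burden$proportional_burden) &
                burden$tissue %in% c("adenoma", "carcinoma"), ]
  if (length(unique(b$tissue)) < 2)
    stop("need both adenoma and carcinoma samples", call. = FALSE)
  res <- patientRandomEffectTest(b$proportional_burden, b$patient_id,
                                 factor(b$tissue,
                                        levels = c("adenoma", "carcinoma")))
  res$data <- b
  res
}
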