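## Genetic immune-escape calling: HLA mutations (with second-tier rescue),
## HLA loss of heterozygosity, antigen-presenting gene disruption and
## checkpoint overexpression; sample labels and cancer-level clonality.

.escapeKinds <- c("hla_snv", "hla_frameshift", "hla_stopgain", "hla_loh",
                  "apg_high_impact", "apg_snv", "checkpoint_high",
                  "checkpoint_moderate")
.sufficientKinds <- c("hla_loh", "hla_frameshift", "hla_stopgain",
                      "apg_high_impact", "checkpoint_high")
.snvKinds <- c("hla_snv", "apg_snv")

#' HLA loss-of-heterozygosity decision rule
#'
#' Combines allelic-imbalance and allele-specific copy-number evidence per
#' allele state row. An allele is in allelic imbalance (AI) when
#' \code{ai_pvalue < 0.01}. AI alleles are LOH when the lost-allele copy
#' number is below 0.5 with its confidence interval strictly below 0.7, the
#' kept-allele copy number is above 0.75 and more than 10 sites mismatch
#' between the alleles. Independently, a minor allele copy number of 0 from
#' the allele-specific caller marks a candidate LOH. When both sources
#' report, agreement yields LOH; disagreement yields LOH only when the
#' \code{corroborated} flag (manual copy-number inspection) is set. When the
#' minor-allele column is absent (\code{NA}), the combined criteria decide
#' alone.
#'
#' @param states data.frame of HLA allele states (see
#'   [GlandCohort-class] for columns); \code{corroborated} and
#'   \code{minor_allele_cn} may be missing.
#' @param ai_p,cn_lost_max,ci_high_max,cn_kept_min,mismatch_min Decision
#'   thresholds.
#' @return Character vector per row: \code{"loh"},
#'   \code{"allelic_imbalance"}, \code{"none"}, or \code{NA} when neither
#'   AI nor copy-number evidence is available.
#' @export
callHlaLoh <- function(states, ai_p = 0.01, cn_lost_max = 0.5,
                       ci_high_max = 0.7, cn_kept_min = 0.75,
                       mismatch_min = 10) {
  n <- nrow(states)
  minor <- states$minor_allele_cn %||% rep(NA_integer_, n)
  corr <- states$corroborated %||% rep(FALSE, n)
  corr[is.na(corr)] <- FALSE
  aiP <- states$ai_pvalue
  noEvid <- is.na(aiP) & is.na(minor)
  if (any(noEvid))
    warning("HLA state rows without AI or copy-number evidence are not evaluable",
            call. = FALSE)
  ai <- !is.na(aiP) & aiP < ai_p
  crit <- ai & !is.na(states$cn_lost) & states$cn_lost < cn_lost_max &
    !is.na(states$ci_high) & states$ci_high < ci_high_max &
    !is.na(states$cn_kept) & states$cn_kept > cn_kept_min &
    !is.na(states$mismatch_sites) & states$mismatch_sites > mismatch_min
  seqCand <- !is.na(minor) & minor == 0
  loh <- (crit & (is.na(minor) | seqCand)) |
    ((crit | seqCand) & corr)
  out <- ifelse(loh, "loh", ifelse(ai, "allelic_imbalance", "none"))
  out[noEvid] <- NA_character_
  out
}

#' Second-tier rescue of sub-threshold HLA mutations
#'
#' A candidate HLA mutation that fails read-support filters is accepted
#' when the exact same nucleotide change passes filters in another biopsy
#' of the same tumour (and only then); accepted calls carry evidence tier
#' \code{second_tier_rescued}.
#'
#' @param candidates data.frame of sub-threshold calls with
#'   \code{patient_id}, \code{sample_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param confirmed data.frame of filter-passing calls, same columns.
#' @return Logical vector: accepted per candidate row.
#' @export
rescueSecondTierHla <- function(candidates, confirmed) {
  if (!nrow(candidates)) return(logical(0))
  key <- function(df) paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  ckey <- key(candidates)
  fkey <- key(confirmed)
  vapply(seq_len(nrow(candidates)), function(i) {
    hit <- fkey == ckey[i] &
      confirmed$sample_id != candidates$sample_id[i]
    any(hit)
  }, logical(1))
}

#' Expression filter for escape-eligible APGs
#'
#' Restricts the antigen-presenting gene set to genes clearly expressed
#' (TPM at or above \code{tpm_min}) in at least \code{sample_frac} of
#' samples. Genes absent from the matrix are retained with a warning
#' (no evidence to exclude them).
#'
#' @param tpm TPM-like gene x sample matrix.
#' @param apg Character vector of candidate APGs (default [apgGenes()]).
#' @param tpm_min,sample_frac Filter thresholds.
#' @return Character vector of retained genes.
#' @export
apgExpressionFilter <- function(tpm, apg = apgGenes(), tpm_min = 10,
                                sample_frac = 0.05) {
  missing <- setdiff(apg, rownames(tpm))
  if (length(missing))
    warning("APG(s) absent from expression matrix retained without evidence: ",
            paste(missing, collapse = ", "), call. = FALSE)
  present <- intersect(apg, rownames(tpm))
  frac <- rowMeans(tpm[present, , drop = FALSE] >= tpm_min)
  keep <- present[frac >= sample_frac]
  c(keep, missing)
}

#' Checkpoint expression tier per tumour sample
#'
#' Compares PD-L1 (\code{CD274}) and CTLA-4 (\code{CTLA4}) expression on
#' the variance-stabilised scale against the normal-sample pool:
#' \code{high} above mean(normal) + 2 SD(normal), \code{moderate} within
#' (+1 SD, +2 SD]. Under the \code{"or"} rule either gene suffices; under
#' \code{"and"} both genes must reach the tier.
#'
#' @param cohort A [GlandCohort-class] with a VST matrix.
#' @param rule \code{"or"} (default) or \code{"and"}.
#' @param genes Checkpoint gene symbols.
#' @return Named character vector (\code{high}/\code{moderate}/\code{none})
#'   over tumour samples.
#' @export
checkpointTier <- function(cohort, rule = c("or", "and"),
                           genes = c("CD274", "CTLA4")) {
  rule <- match.arg(rule)
  vst <- expressionMatrix(cohort, "vst")
  sm <- cohortSamples(cohort)
  normals <- intersect(colnames(vst), sm$sample_id[sm$tissue == "normal"])
  tumors <- intersect(colnames(vst), sm$sample_id[sm$tissue != "normal"])
  if (!length(normals))
    stop("checkpoint tiers need normal samples in the expression matrix")
  genes <- intersect(genes, rownames(vst))
  if (!length(genes)) stop("checkpoint genes absent from expression matrix")
  z <- sapply(genes, function(g) {
    mu <- mean(vst[g, normals]); sg <- stats::sd(vst[g, normals])
    (vst[g, tumors] - mu) / sg
  })
  z <- matrix(z, nrow = length(tumors), dimnames = list(tumors, genes))
  tier1 <- ifelse(z > 2, "high", ifelse(z > 1, "moderate", "none"))
  comb <- function(v) {
    if (rule == "or") {
      if (any(v == "high")) "high"
      else if (any(v == "moderate")) "moderate" else "none"
    } else {
      if (all(v == "high")) "high"
      else if (all(v %in% c("high", "moderate"))) "moderate" else "none"
    }
  }
  out <- apply(tier1, 1, comb)
  stats::setNames(as.character(out), tumors)
}

#' Enumerate genetic escape mechanisms per sample
#'
#' Derives the mechanism table feeding [classifyEscape()]: HLA class-I
#' mutations by consequence (frameshift, stop-gain, otherwise SNV-class),
#' HLA LOH from the allele-state decision rule, high-impact or
#' at-least-moderate SNV alterations in expression-retained APGs, and
#' checkpoint overexpression tiers.
#'
#' @param cohort A [GlandCohort-class].
#' @param checkpointRule \code{"or"} or \code{"and"}.
#' @return data.frame with \code{sample_id}, \code{kind}, \code{detail},
#'   \code{evidence_tier}.
#' @export
callEscapeMechanisms <- function(cohort, checkpointRule = c("or", "and")) {
  checkpointRule <- match.arg(checkpointRule)
  mu <- cohortMutations(cohort)
  gt <- cohortGenotypes(cohort)
  gt <- gt[gt$present, ]
  rows <- list()
  addRows <- function(ids, kind, detail, tier = "primary") {
    if (!length(ids)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = ids, kind = kind, detail = detail,
      evidence_tier = tier, stringsAsFactors = FALSE)
  }
  ## HLA mutations
  hmu <- mu[mu$gene %in% .hlaClassI() & .proteinChanging(mu$consequence), ]
  if (nrow(hmu)) {
    kind <- ifelse(hmu$consequence == "frameshift", "hla_frameshift",
                   ifelse(hmu$consequence == "nonsense", "hla_stopgain",
                          "hla_snv"))
    for (i in seq_len(nrow(hmu))) {
      sams <- gt$sample_id[gt$mutation_id == hmu$mutation_id[i]]
      addRows(sams, kind[i], hmu$gene[i])
    }
  }
  ## HLA LOH
  hs <- hlaStates(cohort)
  if (.hasTable(hs)) {
    call <- suppressWarnings(callHlaLoh(hs))
    idx <- which(!is.na(call) & call == "loh")
    addRows(hs$sample_id[idx], "hla_loh", hs$allele[idx])
  }
  ## APG mutations (HLA class I handled above)
  tpm <- expressionMatrix(cohort, "tpm")
  apg <- setdiff(apgGenes(), .hlaClassI())
  if (.hasMatrix(tpm)) apg <- apgExpressionFilter(tpm, apg)
  amu <- mu[mu$gene %in% apg & .proteinChanging(mu$consequence), ]
  if (nrow(amu)) {
    impact <- amu$impact %||% rep("moderate", nrow(amu))
    hi <- amu$consequence %in% c("frameshift", "nonsense", "splice")
    snv <- amu$consequence == "missense" & impact %in% c("moderate", "high")
    for (i in seq_len(nrow(amu))) {
      if (!hi[i] && !snv[i]) next
      sams <- gt$sample_id[gt$mutation_id == amu$mutation_id[i]]
      addRows(sams, if (hi[i]) "apg_high_impact" else "apg_snv", amu$gene[i])
    }
  }
  ## checkpoint overexpression
  if (.hasMatrix(expressionMatrix(cohort, "vst"))) {
    tier <- checkpointTier(cohort, checkpointRule)
    addRows(names(tier)[tier == "high"], "checkpoint_high", "CD274/CTLA4")
    addRows(names(tier)[tier == "moderate"], "checkpoint_moderate",
            "CD274/CTLA4")
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), kind = character(0),
                      detail = character(0), evidence_tier = character(0)))
  do.call(rbind, rows)
}

#' Escape label from a sample's mechanism set
#'
#' Deterministic truth table: a sample is \code{escaped} with any of HLA
#' LOH, HLA frameshift, HLA stop-gain, a high-impact APG alteration, at
#' least two SNV-class mechanism instances, or high checkpoint expression;
#' \code{potential_escape} with exactly one SNV-class mechanism or moderate
#' checkpoint expression; otherwise \code{none}.
#'
#' @param kinds Character vector of mechanism kinds carried by one sample
#'   (may repeat; checkpoint tiers enter as \code{checkpoint_high} /
#'   \code{checkpoint_moderate}).
#' @return \code{"escaped"}, \code{"potential_escape"} or \code{"none"}.
#' @export
classifyEscape <- function(kinds) {
  bad <- setdiff(kinds, .escapeKinds)
  if (length(bad)) stop("unknown mechanism kind: ", bad[1])
  nSnv <- sum(kinds %in% .snvKinds)
  if (any(kinds %in% .sufficientKinds) || nSnv >= 2) return("escaped")
  if (nSnv == 1 || any(kinds == "checkpoint_moderate"))
    return("potential_escape")
  "none"
}

#' Per-sample escape labels for a cohort
#'
#' @param cohort A [GlandCohort-class].
#' @param mechanisms Optional precomputed [callEscapeMechanisms()] table.
#' @param checkpointRule Passed to [callEscapeMechanisms()].
#' @return data.frame with \code{sample_id}, \code{patient_id},
#'   \code{label}.
#' @export
sampleEscapeLabels <- function(cohort, mechanisms = NULL,
                               checkpointRule = "or") {
  if (is.null(mechanisms))
    mechanisms <- callEscapeMechanisms(cohort, checkpointRule)
  sm <- cohortSamples(cohort)
  tum <- sm[sm$tissue != "normal", ]
  lab <- vapply(tum$sample_id, function(s) {
    classifyEscape(mechanisms$kind[mechanisms$sample_id == s])
  }, character(1))
  data.frame(sample_id = tum$sample_id, patient_id = tum$patient_id,
             label = unname(lab), stringsAsFactors = FALSE)
}

#' Cancer-level escape clonality summary
#'
#' For every cancer, shared escape-grade mechanisms (those sufficient for
#' the \code{escaped} label on their own) are classified by how widely
#' they are shared across deep-sequenced carcinoma samples: \code{clonal}
#' when present in all, \code{minor_subclonal} when present in fewer than
#' \code{minor_frac} of samples, \code{subclonal} otherwise, and
#' \code{none} when no such mechanism exists. \code{epigenetic_only} marks
#' cancers without genetic escape that carry at least one APG promoter
#' accessibility loss.
#'
#' @param cohort A [GlandCohort-class].
#' @param mechanisms Optional precomputed mechanism table.
#' @param apgScaaLoss Optional character vector of patient ids with >= 1
#'   APG promoter accessibility loss (from the chromatin module).
#' @param minor_frac Minor-subclone threshold (fraction of samples,
#'   exclusive).
#' @param checkpointRule Passed to [callEscapeMechanisms()].
#' @return data.frame with \code{patient_id}, \code{escape_clonality},
#'   \code{epigenetic_only}.
#' @export
cancerEscapeSummary <- function(cohort, mechanisms = NULL,
                                apgScaaLoss = character(0),
                                minor_frac = 0.25, checkpointRule = "or") {
  if (is.null(mechanisms))
    mechanisms <- callEscapeMechanisms(cohort, checkpointRule)
  sm <- cohortSamples(cohort)
  deep <- sm[sm$tissue == "carcinoma" & sm$assay == "wgs_deep", ]
  res <- lapply(split(deep, deep$patient_id), function(d) {
    mech <- mechanisms[mechanisms$sample_id %in% d$sample_id &
                         mechanisms$kind %in% .sufficientKinds, ]
    if (!nrow(mech)) {
      cls <- "none"
    } else {
      key <- paste(mech$kind, mech$detail)
      frac <- vapply(split(mech$sample_id, key),
                     function(s) length(unique(s)) / nrow(d), numeric(1))
      cls <- if (any(frac == 1)) "clonal"
      else if (max(frac) < minor_frac) "minor_subclonal"
      else "subclonal"
    }
    data.frame(patient_id = d$patient_id[1], escape_clonality = cls,
               epigenetic_only = cls == "none" &
                 d$patient_id[1] %in% apgScaaLoss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
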