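## End-to-end orchestration: simulate/load -> validate -> burden -> scaa ->
## escape -> editing -> dnds -> selection, under one threshold bundle.

#' Default analysis thresholds
#'
#' Every decision constant used by the pipeline, exposed as a single named
#' list so sensitivity analyses are one-line edits. Defaults are the
#' published operating points: accessibility loss below -1 / gain above 1
#' (log2), allelic-imbalance p < 0.01, lost-allele copy number < 0.5 with
#' CI high < 0.7, kept-allele copy number > 0.75, > 10 mismatched sites,
#' APG expression filter >= 10 TPM in >= 5\% of samples, expressed >= 3
#' alt reads, edited depth > 10 with 0 alt, VAF window (0.05, 0.1),
#' promoter/TF windows 1000 bp, 200 permutations with set sizes 25--40,
#' minor subclone < 25\%.
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(scaa_loss = -1, scaa_gain = 1,
       ai_p = 0.01, cn_lost_max = 0.5, ci_high_max = 0.7,
       cn_kept_min = 0.75, mismatch_min = 10,
       tpm_min = 10, tpm_sample_frac = 0.05,
       expressed_min_alt = 3, edited_min_depth = 10,
       vaf_window = c(0.05, 0.1),
       promoter_window = 1000, tf_window = 1000,
       n_perm = 200, perm_set_size = c(25, 40),
       minor_subclone_frac = 0.25,
       checkpoint_rule = "or",
       editing_min_samples = 2)
}

.stageTry <- function(expr, stage, results) {
  tryCatch(expr, error = function(e) {
    warning(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            call. = FALSE)
    list(failed = TRUE, message = conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every enabled stage in dependency order on a cohort (supplied
#' or simulated from a config) and returns the consolidated result bundle.
#' A failing stage records its error and the remaining stages continue.
#'
#' @param cohort A [GlandCohort-class]; or \code{NULL} to simulate.
#' @param sim_config A [simConfig()] used when \code{cohort} is NULL.
#' @param thresholds Threshold bundle (see [defaultThresholds()]).
#' @param stages Character subset of \code{c("burden", "scaa", "escape",
#'   "editing", "dnds", "selection")}.
#' @param seed Seed for the permutation stage.
#' @return Named list of stage outputs, plus \code{truth} when simulated.
#' @export
runPipeline <- function(cohort = NULL, sim_config = simConfig(),
                        thresholds = defaultThresholds(),
                        stages = c("burden", "scaa", "escape", "editing",
                                   "dnds", "selection"),
                        seed = 1L) {
  th <- utils::modifyList(defaultThresholds(), thresholds)
  res <- list(thresholds = th, seed = seed)
  if (is.null(cohort)) {
    sim <- simulateCohort(sim_config)
    cohort <- sim$cohort
    res$truth <- sim$truth
  }
  methods::validObject(cohort)
  res$cohort <- cohort
  clon <- .stageTry(classifyClonality(cohort), "clonality", res)
  res$clonality <- clon
  if ("burden" %in% stages) {
    res$burden <- .stageTry({
      b <- proportionalBurden(cohort, "snv_only")
      out <- list(per_sample = b)
      if (length(unique(b$tissue)) > 1)
        out$cra_vs_crc <- craVsCrcBurdenTest(b)
      out
    }, "burden", res)
  }
  scaa <- NULL
  if ("scaa" %in% stages && hasAtac(cohort)) {
    res$scaa <- .stageTry({
      calls <- scaaCalls(cohort, th$scaa_loss, th$scaa_gain,
                         th$promoter_window)
      prom <- promoterRegions(cohort)
      universe <- unique(prom$name)
      loss_bias <- apgLossBiasTest(calls, apgGenes(), universe,
                                   n_perm = th$n_perm,
                                   size_range = th$perm_set_size,
                                   seed = seed)
      assoc <- neoantigenScaaAssociation(cohort, calls)
      prop <- tryCatch(perCancerScaaProportion(cohort, calls),
                       error = function(e) NULL)
      tf <- tfLossSiteEnrichment(cohort, calls, window = th$tf_window)
      list(calls = calls, loss_bias = loss_bias, association = assoc,
           per_cancer = prop, tf = tf)
    }, "scaa", res)
    if (!isTRUE(res$scaa$failed)) scaa <- res$scaa$calls
  }
  if ("escape" %in% stages) {
    res$escape <- .stageTry({
      mech <- callEscapeMechanisms(cohort, th$checkpoint_rule)
      labels <- sampleEscapeLabels(cohort, mech)
      apgLoss <- character(0)
      if (!is.null(scaa)) {
        s <- scaa[scaa$direction == "loss" &
                    scaa$region_class == "promoter" &
                    scaa$gene %in% apgGenes(), ]
        apgLoss <- unique(s$cancer_id)
      }
      summary <- cancerEscapeSummary(cohort, mech, apgLoss,
                                     th$minor_subclone_frac)
      list(mechanisms = mech, sample_labels = labels,
           cancer_summary = summary)
    }, "escape", res)
  }
  if ("editing" %in% stages && hasRnaSupport(cohort)) {
    res$editing <- .stageTry({
      calls <- expressionCalls(cohort)
      cl <- if (isTRUE(clon$failed)) NULL else clon
      list(summary = editingSummary(cohort, calls, cl,
                                    th$editing_min_samples),
           or_all = editingOddsRatio(cohort, calls, "all",
                                     min_samples = th$editing_min_samples),
           or_clonal = if (!is.null(cl))
             editingOddsRatio(cohort, calls, "clonal", cl,
                              min_samples = th$editing_min_samples))
    }, "editing", res)
  }
  if ("dnds" %in% stages && !is.null(immunopeptidomeRegions(cohort))) {
    res$dnds <- .stageTry({
      d <- immuneDndsPerSample(cohort)
      list(per_sample = d,
           median_immune_dnds = stats::median(d$immune_dnds[d$eligible],
                                              na.rm = TRUE))
    }, "dnds", res)
  }
  if ("selection" %in% stages) {
    res$selection <- .stageTry({
      mu <- cohortMutations(cohort)
      gt <- cohortGenotypes(cohort)
      gt <- gt[gt$present, ]
      hi <- mu$immunogenicity_tier[match(gt$mutation_id,
                                         mu$mutation_id)] == "high"
      neo <- .isNeoantigen(mu$strong_binder_count[match(gt$mutation_id,
                                                        mu$mutation_id)])
      ks <- vafDepletionKS(gt$vaf[neo], gt$vaf[!neo])
      win <- tryCatch(
        subcloneWindowTest(gt$vaf, hi, gt$sample_id, th$vaf_window),
        error = function(e) NULL)
      b <- proportionalBurden(cohort, "snv_only")
      b <- merge(b, cohortSamples(cohort)[, c("sample_id", "region",
                                              "purity")],
                 by = "sample_id")
      reg <- proportionRegression(b)
      list(vaf_ks = ks, window = win, regression = reg)
    }, "selection", res)
  }
  res
}

#' Write a markdown report of a pipeline run
#'
#' @param results Output of [runPipeline()].
#' @param file Output path (markdown).
#' @return Invisibly, the file path.
#' @export
writePipelineReport <- function(results, file) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  L <- c("# Immune evasion pipeline report", "")
  co <- results$cohort
  L <- c(L, sprintf("Cohort: %d patients, %d samples, %d mutations.",
                    nrow(cohortPatients(co)), nrow(cohortSamples(co)),
                    nrow(cohortMutations(co))), "")
  if (!is.null(results$burden) && !isTRUE(results$burden$failed)) {
    b <- results$burden$per_sample
    L <- c(L, "## Proportional neoantigen burden (SNV-only)",
           sprintf("Median burden: %s across %d samples.",
                   fmt(stats::median(b$proportional_burden, na.rm = TRUE)),
                   nrow(b)))
    if (!is.null(results$burden$cra_vs_crc))
      L <- c(L, sprintf("Adenoma vs carcinoma mixed-model p = %s.",
                        fmt(results$burden$cra_vs_crc$p_value)))
    L <- c(L, "")
  }
  if (!is.null(results$scaa) && !isTRUE(results$scaa$failed)) {
    s <- results$scaa
    L <- c(L, "## Chromatin accessibility alterations",
           sprintf("APG promoter SCAAs: %d losses, %d gains; permutation p = %s.",
                   s$loss_bias$observed_loss, s$loss_bias$observed_gain,
                   fmt(s$loss_bias$p_value)),
           sprintf("Neoantigen x SCAA-loss OR = %s (%s-%s), p = %s.",
                   fmt(s$association$or), fmt(s$association$ci_low),
                   fmt(s$association$ci_high), fmt(s$association$p_value)),
           "")
  }
  if (!is.null(results$escape) && !isTRUE(results$escape$failed)) {
    cs <- results$escape$cancer_summary
    L <- c(L, "## Immune escape",
           sprintf("Escape clonality: %s.",
                   paste(sprintf("%s=%d", names(table(cs$escape_clonality)),
                                 as.integer(table(cs$escape_clonality))),
                         collapse = ", ")), "")
  }
  if (!is.null(results$editing) && !isTRUE(results$editing$failed)) {
    e <- results$editing$or_all
    L <- c(L, "## Transcriptional editing",
           sprintf("Editing OR (all mutations) = %s (%s-%s), p = %s.",
                   fmt(e$or), fmt(e$ci_low), fmt(e$ci_high),
                   fmt(e$p_value)), "")
  }
  if (!is.null(results$dnds) && !isTRUE(results$dnds$failed)) {
    L <- c(L, "## Immune dN/dS",
           sprintf("Median immune dN/dS across eligible samples: %s.",
                   fmt(results$dnds$median_immune_dnds)), "")
  }
  if (!is.null(results$selection) && !isTRUE(results$selection$failed)) {
    sel <- results$selection
    L <- c(L, "## Intratumour selection",
           sprintf("Neoantigen VAF depletion KS p = %s.",
                   fmt(sel$vaf_ks$p_value)))
    if (!is.null(sel$window))
      L <- c(L, sprintf("Small-subclone window test p = %s.",
                        fmt(sel$window$p_value)))
    L <- c(L, "")
  }
  writeLines(L, file)
  invisible(file)
}
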