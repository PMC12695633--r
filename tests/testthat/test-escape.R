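lohState <- function(ai = 0.005, cn_lost = 0.30, ci_low = 0.10,
                     ci_high = 0.60, cn_kept = 0.90, mism = 15,
                     minor = NA_integer_, corr = FALSE) {
  data.frame(patient_id = "P1", sample_id = "P1_G1", allele = "hla_a_01_01",
             ai_pvalue = ai, cn_lost = cn_lost, ci_low = ci_low,
             ci_high = ci_high, cn_kept = cn_kept, mismatch_sites = mism,
             minor_allele_cn = minor, corroborated = corr,
             stringsAsFactors = FALSE)
}

test_that("the HLA LOH decision reproduces the combined criteria", {
  expect_identical(callHlaLoh(lohState()), "loh")
  # CI reaching 0.7 or above blocks LOH but keeps allelic imbalance
  expect_identical(callHlaLoh(lohState(ci_high = 0.75)),
                   "allelic_imbalance")
  # failing the AI gate blocks everything
  expect_identical(callHlaLoh(lohState(ai = 0.02)), "none")
  # boundary: criteria are strict inequalities
  expect_identical(callHlaLoh(lohState(cn_lost = 0.5)),
                   "allelic_imbalance")
  expect_identical(callHlaLoh(lohState(cn_kept = 0.75)),
                   "allelic_imbalance")
  expect_identical(callHlaLoh(lohState(mism = 10)), "allelic_imbalance")
  # allele-specific caller disagreement is settled by corroboration
  expect_identical(callHlaLoh(lohState(minor = 1L)), "allelic_imbalance")
  expect_identical(callHlaLoh(lohState(minor = 1L, corr = TRUE)), "loh")
  expect_identical(callHlaLoh(lohState(minor = 0L)), "loh")
  # candidate LOH from copy number alone needs corroboration
  expect_identical(callHlaLoh(lohState(ai = 0.5, minor = 0L)), "none")
  expect_identical(callHlaLoh(lohState(ai = 0.5, minor = 0L, corr = TRUE)),
                   "loh")
  # no evidence at all is not evaluable
  expect_warning(r <- callHlaLoh(lohState(ai = NA, minor = NA_integer_)),
                 "not evaluable")
  expect_true(is.na(r))
})

test_that("the LOH decision is monotone under criterion worsening", {
  base <- lohState()
  worsen <- list(
    function(s) { s$ai_pvalue <- s$ai_pvalue * 10; s },
    function(s) { s$ci_high <- s$ci_high + 0.2; s },
    function(s) { s$cn_lost <- s$cn_lost + 0.3; s },
    function(s) { s$cn_kept <- s$cn_kept - 0.3; s },
    function(s) { s$mismatch_sites <- s$mismatch_sites - 10L; s })
  rank <- function(x) match(x, c("none", "allelic_imbalance", "loh"))
  set.seed(1)
  for (i in 1:200) {
    s <- lohState(ai = runif(1, 0, 0.05), cn_lost = runif(1, 0, 0.6),
                  ci_high = runif(1, 0.3, 0.9),
                  cn_kept = runif(1, 0.5, 1.2),
                  mism = sample(0:30, 1))
    s$ci_low <- min(s$ci_low, s$cn_lost)
    s$ci_high <- max(s$ci_high, s$cn_lost)
    before <- callHlaLoh(s)
    for (w in worsen) {
      s2 <- w(s)
      s2$ci_high <- max(s2$ci_high, s2$cn_lost)
      s2$ci_low <- min(s2$ci_low, s2$cn_lost)
      expect_lte(rank(callHlaLoh(s2)), rank(before))
    }
  }
})

test_that("second-tier HLA mutations are rescued only from the same tumour", {
  cand <- data.frame(patient_id = "P1", sample_id = "P1_G1", chrom = "chr6",
                     pos = 100L, ref = "C", alt = "T")
  confSame <- data.frame(patient_id = "P1", sample_id = "P1_G2",
                         chrom = "chr6", pos = 100L, ref = "C", alt = "T")
  confOther <- data.frame(patient_id = "P2", sample_id = "P2_G1",
                          chrom = "chr6", pos = 100L, ref = "C", alt = "T")
  confSelf <- data.frame(patient_id = "P1", sample_id = "P1_G1",
                         chrom = "chr6", pos = 100L, ref = "C", alt = "T")
  expect_true(rescueSecondTierHla(cand, confSame))
  expect_false(rescueSecondTierHla(cand, confOther))
  expect_false(rescueSecondTierHla(cand, confSelf))   # needs another biopsy
  expect_false(rescueSecondTierHla(cand,
                                   transform(confSame, alt = "G")))
})

test_that("the APG expression filter applies the TPM rule exactly", {
  tpm <- matrix(0, nrow = 3, ncol = 100,
                dimnames = list(c("TAP1", "TAP2", "B2M"), NULL))
  tpm["TAP1", 1:10] <- 12     # 10% of samples at 12 TPM -> retained
  tpm["TAP2", 1:2] <- 12      # 2% of samples -> removed
  tpm["B2M", ] <- 9.9         # never reaches 10 TPM -> removed
  keep <- apgExpressionFilter(tpm, c("TAP1", "TAP2", "B2M"))
  expect_identical(keep, "TAP1")
  # boundary: exactly 5% of samples at exactly 10 TPM is retained
  tpm["TAP2", 1:5] <- 10
  expect_true("TAP2" %in% apgExpressionFilter(tpm, c("TAP1", "TAP2")))
  # absent gene retained with a warning
  expect_warning(keep2 <- apgExpressionFilter(tpm, c("TAP1", "NLRC5")),
                 "NLRC5")
  expect_true("NLRC5" %in% keep2)
})

test_that("escape labels follow the published truth table", {
  expect_identical(classifyEscape("hla_frameshift"), "escaped")
  expect_identical(classifyEscape("hla_loh"), "escaped")
  expect_identical(classifyEscape("hla_stopgain"), "escaped")
  expect_identical(classifyEscape("apg_high_impact"), "escaped")
  expect_identical(classifyEscape("checkpoint_high"), "escaped")
  expect_identical(classifyEscape("apg_snv"), "potential_escape")
  expect_identical(classifyEscape("hla_snv"), "potential_escape")
  expect_identical(classifyEscape("checkpoint_moderate"), "potential_escape")
  expect_identical(classifyEscape(c("hla_snv", "apg_snv")), "escaped")
  expect_identical(classifyEscape(c("apg_snv", "apg_snv")), "escaped")
  expect_identical(classifyEscape(character(0)), "none")
  expect_error(classifyEscape("mystery"), "unknown mechanism")
})

test_that("checkpoint tiers use the normal pool, with OR vs AND rules", {
  sim <- simulateCohort(simConfig(n_patients = 3, seed = 6,
                                  escape_plan = rep("none", 3)))
  co <- sim$cohort
  vst <- expressionMatrix(co, "vst")
  sm <- cohortSamples(co)
  tum <- sm$sample_id[sm$tissue != "normal"]
  # push one sample's PD-L1 (only) above +2 SD of the normal pool
  vst["CD274", tum[1]] <- 6 + 0.4 * 5
  vst["CTLA4", tum[1]] <- 6
  co2 <- GlandCohort(cohortPatients(co), sm, cohortMutations(co),
                     cohortGenotypes(co), vst = vst)
  expect_identical(unname(checkpointTier(co2, "or")[tum[1]]), "high")
  expect_identical(unname(checkpointTier(co2, "and")[tum[1]]), "none")
  # moderate band (1, 2] SD on a single gene
  vst["CD274", tum[2]] <- 6 + 0.4 * 1.5
  co3 <- GlandCohort(cohortPatients(co), sm, cohortMutations(co),
                     cohortGenotypes(co), vst = vst)
  expect_identical(unname(checkpointTier(co3, "or")[tum[2]]), "moderate")
})

test_that("cancer-level escape clonality uses full sharing and the <25% rule", {
  sm <- data.frame(sample_id = sprintf("P1_G%d", 1:10), patient_id = "P1",
                   tissue = "carcinoma", region = "gland",
                   assay = "wgs_deep", purity = 0.7)
  pt <- tinyPatients()[1, ]
  mu <- tinyMutation("M1", "P1")
  gt <- tinyGenotype("M1", "P1_G1")
  co <- GlandCohort(pt, sm, mu, gt)
  mk <- function(n) data.frame(sample_id = sprintf("P1_G%d", seq_len(n)),
                               kind = "hla_loh", detail = "hla_a_01_01",
                               evidence_tier = "primary")
  expect_identical(cancerEscapeSummary(co, mk(10))$escape_clonality,
                   "clonal")
  expect_identical(cancerEscapeSummary(co, mk(2))$escape_clonality,
                   "minor_subclonal")
  expect_identical(cancerEscapeSummary(co, mk(5))$escape_clonality,
                   "subclonal")
  # epigenetic-only flag on cancers without genetic escape
  none <- mk(1)[0, ]
  cs <- cancerEscapeSummary(co, none, apgScaaLoss = "P1")
  expect_identical(cs$escape_clonality, "none")
  expect_true(cs$epigenetic_only)
})

test_that("synthetic escape labels and clonality classes match the plan", {
  for (s in c(2, 9)) {
    sim <- simulateCohort(simConfig(n_patients = 6, seed = s))
    lab <- sampleEscapeLabels(sim$cohort)
    m <- merge(lab, sim$truth$samples, by = "sample_id")
    expect_identical(m$label == "escaped", m$escape_label == "escaped")
    cs <- cancerEscapeSummary(sim$cohort)
    cm <- merge(cs, sim$truth$patients, by = "patient_id")
    expect_identical(cm$escape_clonality, cm$escape_class)
  }
})
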