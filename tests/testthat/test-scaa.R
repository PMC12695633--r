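grWith <- function(start, end, name, strand = "*") {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                         strand = strand, name = name)
}

test_that("SCAA direction thresholds match the published cutoffs", {
  expect_identical(callScaa(-1.2), "loss")
  expect_identical(callScaa(1.5), "gain")
  expect_identical(callScaa(-0.8), "none")
  # thresholds are strict
  expect_identical(callScaa(c(-1, 1)), c("none", "none"))
  expect_error(callScaa(NaN), "non-finite")
  expect_error(callScaa(Inf), "non-finite")
})

test_that("promoter assignment is strand-aware, windowed and tie-broken", {
  # plus-strand gene: TSS at interval start
  prom <- grWith(10000, 10999, "GENEA", "+")
  expect_identical(assignPromoter(grWith(9400, 9500, "pk"), prom), "GENEA")
  # 1500 bp away from the only TSS: unassigned
  expect_identical(assignPromoter(grWith(8000, 8499, "pk"), prom), "")
  # minus-strand gene: TSS at interval end
  promM <- grWith(10000, 10999, "GENEB", "-")
  expect_identical(assignPromoter(grWith(11200, 11300, "pk"), promM),
                   "GENEB")
  expect_identical(assignPromoter(grWith(9600, 9700, "pk"), promM), "")
  # equidistant TSS pair (800 bp either side): lexicographically smaller
  # symbol wins
  prom2 <- c(grWith(1399, 2398, "ZZZ", "+"), grWith(3201, 4200, "AAA", "+"))
  peak <- grWith(2200, 2400, "pk")
  expect_identical(assignPromoter(peak, prom2), "AAA")
  # nearest wins when distances differ
  prom3 <- c(grWith(1599, 2598, "ZZZ", "+"), grWith(3201, 4200, "AAA", "+"))
  expect_identical(assignPromoter(grWith(2200, 2400, "pk"), prom3), "ZZZ")
})

test_that("promoter assignment is invariant under strand mirroring", {
  set.seed(4)
  L <- 100000L
  tssPos <- sort(sample(5000:95000, 20))
  strand <- sample(c("+", "-"), 20, replace = TRUE)
  start <- ifelse(strand == "+", tssPos, tssPos - 999L)
  prom <- grWith(start, start + 999L, sprintf("G%02d", 1:20), strand)
  ps <- sample(1000:99000, 30)
  peaks <- grWith(ps, ps + 200L, sprintf("pk%02d", 1:30))
  a <- assignPromoter(peaks, prom)
  # mirror all coordinates and flip strands
  flip <- function(s, e) list(start = L - e, end = L - s)
  fp <- flip(GenomicRanges::start(prom), GenomicRanges::end(prom))
  promF <- grWith(fp$start, fp$end, prom$name,
                  ifelse(strand == "+", "-", "+"))
  fk <- flip(GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaksF <- grWith(fk$start, fk$end, peaks$name)
  b <- assignPromoter(peaksF, promF)
  expect_identical(a, b)
})

test_that("cohort-level SCAA calls carry genes and recurrence flags", {
  sim <- simulateCohort(simConfig(n_patients = 4, seed = 13))
  calls <- scaaCalls(sim$cohort)
  expect_true(all(calls$direction %in% c("loss", "gain")))
  expect_true(all(abs(calls$fold_change) > 1))
  # planted SCAAs are recovered: every truth row appears in the calls
  tr <- sim$truth$scaa
  key <- paste(calls$gene, calls$cancer_id, calls$direction)
  expect_true(all(paste(tr$gene, tr$patient_id, tr$direction) %in% key))
  # recurrence = loss of the same peak in more than one patient
  lossTab <- table(calls$peak_id[calls$direction == "loss"])
  expect_identical(sort(unique(calls$peak_id[calls$recurrent])),
                   sort(names(lossTab)[lossTab > 1]))
})

test_that("the loss-bias permutation test uses the add-one estimator", {
  # all APG SCAAs are losses; background split evenly -> observed exceeds
  # essentially every random set
  scaa <- data.frame(
    peak_id = sprintf("pk%03d", 1:300),
    cancer_id = "C1",
    fold_change = c(rep(-2, 40), rep(c(-2, 2), 130)),
    direction = c(rep("loss", 40), rep(c("loss", "gain"), 130)),
    gene = c(rep(apgGenes()[1:20], 2), sprintf("B%03d", 1:260)),
    region_class = "promoter", recurrent = FALSE)
  universe <- c(apgGenes(), sprintf("B%03d", 1:260))
  res <- apgLossBiasTest(scaa, apgGenes(), universe, n_perm = 200, seed = 1)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$p_value, (res$n_more_extreme + 1) / 201)
  expect_lt(res$p_value, 0.05)
  # identical permutations under the same seed
  res2 <- apgLossBiasTest(scaa, apgGenes(), universe, n_perm = 200, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$set_sizes, res2$set_sizes)
  expect_true(all(res$set_sizes >= 25 & res$set_sizes <= 40))
  # all SCAAs losses genome-wide: no bias detectable, p in the 1 region
  scaaAll <- transform(scaa, direction = "loss")
  resAll <- apgLossBiasTest(scaaAll, apgGenes(), universe, n_perm = 200,
                            seed = 2)
  expect_gt(resAll$p_value, 0.9)
  # universe smaller than the maximum set size errors
  expect_error(apgLossBiasTest(scaa, apgGenes(), universe[1:30],
                               n_perm = 10, seed = 1), "universe")
})

test_that("a planted loss bias is detected and the null is calibrated", {
  sim <- simulateCohort(simConfig(n_patients = 6, seed = 19))
  calls <- scaaCalls(sim$cohort)
  uni <- unique(promoterRegions(sim$cohort)$name)
  res <- apgLossBiasTest(calls, apgGenes(), uni, seed = 3)
  expect_lt(res$p_value, 0.05)
  # label exchange: swapping the APG set for a random set of equal size
  # gives unremarkable p most of the time (spot check at a few seeds)
  set.seed(8)
  ps <- vapply(1:5, function(i) {
    fake <- sample(setdiff(uni, apgGenes()), 35)
    apgLossBiasTest(calls, fake, uni, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("neoantigen x SCAA-loss association recovers the planted odds ratio direction", {
  sim <- simulateCohort(simConfig(n_patients = 6, mmrd_fraction = 1,
                                  adenoma_glands = 0, scaa_neo_or = 2.5,
                                  seed = 23))
  calls <- scaaCalls(sim$cohort)
  res <- neoantigenScaaAssociation(sim$cohort, calls)
  expect_gt(res$or, 1)
  expect_lt(res$p_value, 0.05)
  expect_identical(dim(res$table), c(2L, 2L))
  expect_equal(sum(res$table), sum(.proteinChanging(
    cohortMutations(sim$cohort)$consequence)))
})

test_that("per-cancer SCAA proportions are paired and guarded", {
  sim <- simulateCohort(simConfig(n_patients = 4, seed = 29))
  calls <- scaaCalls(sim$cohort)
  res <- perCancerScaaProportion(sim$cohort, calls)
  expect_true(all(c("prop_neoantigen", "prop_nonantigenic") %in%
                    names(res$per_cancer)))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # fewer than 3 cancers is not evaluable
  sim2 <- simulateCohort(simConfig(n_patients = 2, seed = 29))
  calls2 <- scaaCalls(sim2$cohort)
  expect_error(perCancerScaaProportion(sim2$cohort, calls2), "fewer than 3")
})

test_that("TF proximity counting and selection follow the distance rule", {
  peaks <- grWith(c(10000, 20000, 30000, 40000), c(10599, 20599, 30599,
                                                   40599),
                  c("pkA", "pkB", "pkC", "pkD"))
  prom <- grWith(c(10000, 20000, 30000, 40000) - 500,
                 c(10000, 20000, 30000, 40000) + 499,
                 c("TAP1", "TAP2", "B2M", "G0001"), "+")
  # TF1 within 1000 bp of three loss regions; TF2 always at 1200 bp
  tf <- c(grWith(c(10700, 20700, 30700), c(10709, 20709, 30709), "TF1"),
          grWith(c(11800, 21800, 31800, 41800), c(11809, 21809, 31809,
                                                  41809), "TF2"))
  fc <- matrix(c(-2, -2, -2, 0,
                 -2, -2, -2, 0), ncol = 2,
               dimnames = list(c("pkA", "pkB", "pkC", "pkD"), c("C1", "C2")))
  pt <- data.frame(patient_id = c("C1", "C2"), mmr_status = "MMRp",
                   hla_alleles = "hla_a_01_01")
  sm <- data.frame(sample_id = c("C1_G1", "C1_G2", "C2_G1", "C2_G2"),
                   patient_id = rep(c("C1", "C2"), each = 2),
                   tissue = "carcinoma", region = "gland",
                   assay = "wgs_deep", purity = 0.7)
  mu <- tinyMutation("M1", "C1")
  gt <- tinyGenotype("M1", "C1_G1")
  co <- GlandCohort(pt, sm, mu, gt, atacFC = fc, peaks = peaks,
                    promoters = prom, tfSites = tf)
  calls <- scaaCalls(co)
  res <- tfLossSiteEnrichment(co, calls)
  expect_identical(res$n_regions, 3L)   # pkD has no loss; 3 recurrent APGs
  ptf <- res$per_tf
  expect_equal(ptf$n_bound_regions[ptf$tf == "TF1"], 3L)
  expect_equal(ptf$n_bound_regions[ptf$tf == "TF2"], 0L)  # 1200 bp > window
  expect_true(ptf$selected[ptf$tf == "TF1"])    # bound more than two regions
  expect_false(ptf$selected[ptf$tf == "TF2"])
  expect_false(is.null(res$enrichment))
  # distance exactly at the window is excluded (strict rule)
  tf3 <- grWith(11600, 11609, "TF3")   # distance 1000 from pkA end
  co3 <- GlandCohort(pt, sm, mu, gt, atacFC = fc, peaks = peaks,
                     promoters = prom, tfSites = tf3)
  r3 <- tfLossSiteEnrichment(co3, scaaCalls(co3))
  expect_equal(r3$per_tf$n_bound_regions[r3$per_tf$tf == "TF3"], 0L)
  # no recurrent losses -> empty report
  fc1 <- fc; fc1[, 2] <- 0
  co4 <- GlandCohort(pt, sm, mu, gt, atacFC = fc1, peaks = peaks,
                     promoters = prom, tfSites = tf)
  r4 <- tfLossSiteEnrichment(co4, scaaCalls(co4))
  expect_identical(r4$n_regions, 0L)
  expect_identical(nrow(r4$per_tf), 0L)
})
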