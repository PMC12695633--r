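test_that("opportunity building weights sites by the spectrum", {
  cm <- syntheticCodingModel(0.2)
  opp <- buildOpportunities(cm)
  on <- opp[opp$region_class == "ON", ]
  off <- opp[opp$region_class == "OFF", ]
  # uniform spectrum: 3:1 nonsynonymous:synonymous site ratio survives
  expect_equal(on$opp_nonsyn / on$opp_syn, 3)
  expect_equal(off$opp_nonsyn / off$opp_syn, 3)
  # doubling the spectrum leaves every dN/dS ratio unchanged
  sp <- stats::setNames(rep(2, 192), trinucContexts())
  opp2 <- buildOpportunities(cm, sp)
  expect_equal(opp2$opp_nonsyn / opp2$opp_syn, opp$opp_nonsyn / opp$opp_syn)
  # a biased spectrum shifts opportunities when the model is non-uniform
  cm2 <- cm
  cm2$nonsyn_sites[cm2$context == "ACA>AAA"] <- 10
  spb <- stats::setNames(rep(1, 192), trinucContexts())
  spb["ACA>AAA"] <- 5
  oppb <- buildOpportunities(cm2, spb)
  expect_gt(oppb$opp_nonsyn[1] / oppb$opp_syn[1], 3)
  # missing context errors
  expect_error(buildOpportunities(cm, spb[-1]), "context absent")
})

test_that("dN/dS normalises counts by opportunity", {
  expect_equal(computeDnds(3, 1, 3, 1)$dnds, 1)
  expect_equal(computeDnds(6, 1, 3, 1)$dnds, 2)
  z <- computeDnds(5, 0, 3, 1)
  expect_false(z$eligible)
  expect_true(is.na(z$dnds))
})

test_that("immune dN/dS is the ON/OFF ratio with an eligibility guard", {
  opp <- buildOpportunities(syntheticCodingModel(0.5))
  cons <- c(rep("missense", 30), rep("synonymous", 10),
            rep("missense", 60), rep("synonymous", 20))
  on <- c(rep(TRUE, 40), rep(FALSE, 80))
  r <- immuneDnds(cons, on, opp)
  expect_true(r$eligible)
  expect_equal(r$dnds_on, (30 / 3) / (10 / 1) * 1)   # opp ratio 3:1 cancels
  expect_equal(r$immune_dnds, r$dnds_on / r$dnds_off)
  expect_equal(r$immune_dnds, 1)                     # identical composition
  expect_true(r$ci_low < 1 && 1 < r$ci_high)
  # no OFF-target synonymous mutations: excluded
  cons2 <- c(rep("missense", 30), rep("synonymous", 10), rep("missense", 60))
  on2 <- c(rep(TRUE, 40), rep(FALSE, 60))
  expect_false(immuneDnds(cons2, on2, opp)$eligible)
  # global scaling of the mutation load leaves the ratio unchanged
  r2 <- immuneDnds(rep(cons, 3), rep(on, 3), opp)
  expect_equal(r2$immune_dnds, r$immune_dnds)
})

# Brute-force oracle: enumerate every substitution of a toy coding sequence,
# classify synonymous/nonsynonymous by codon translation, and treat the
# full enumeration as the observed mutation set; dN/dS is then exactly 1 in
# both regions, and deleting half the ON nonsynonymous changes halves the
# immune dN/dS exactly.
test_that("immune dN/dS agrees with a per-site enumeration oracle", {
  codons <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L",
              CTC = "L", CTA = "L", CTG = "L", ATT = "I", ATC = "I",
              ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V",
              GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
              CCT = "P", CCC = "P", CCA = "P", CCG = "P", ACT = "T",
              ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
              GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
              TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
              AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D",
              GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
              TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R",
              CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
              GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  set.seed(10)
  n_codon <- 100                       # 300 nt toy CDS
  seqv <- sample(c("A", "C", "G", "T"), 3 * n_codon, replace = TRUE)
  onSites <- seq_len(3 * 30)           # first 30 codons are ON-target
  subs <- list()
  for (i in seq_along(seqv)) {
    if (i == 1 || i == length(seqv)) next  # need full trinucleotide context
    codon_i <- (i - 1) %/% 3 + 1
    cpos <- (i - 1) %% 3 + 1
    cod <- seqv[(codon_i - 1) * 3 + 1:3]
    for (alt in setdiff(c("A", "C", "G", "T"), seqv[i])) {
      cod2 <- cod; cod2[cpos] <- alt
      syn <- codons[paste(cod, collapse = "")] ==
        codons[paste(cod2, collapse = "")]
      ctx <- paste0(seqv[i - 1], seqv[i], seqv[i + 1], ">",
                    seqv[i - 1], alt, seqv[i + 1])
      subs[[length(subs) + 1L]] <- data.frame(
        site = i, context = ctx, syn = unname(syn),
        on = i %in% onSites)
    }
  }
  subs <- do.call(rbind, subs)
  # coding model from the enumeration itself (site counts per context)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(subs))) ~ context + on + syn,
                          data = subs, FUN = sum)
  cm <- do.call(rbind, lapply(split(agg, list(agg$context, agg$on),
                                    drop = TRUE), function(d) {
    data.frame(region_class = if (d$on[1]) "ON" else "OFF",
               context = d$context[1],
               syn_sites = sum(d$n[d$syn]) / 3,
               nonsyn_sites = sum(d$n[!d$syn]) / 3)
  }))
  opp <- buildOpportunities(cm)
  cons <- ifelse(subs$syn, "synonymous", "missense")
  r <- immuneDnds(cons, subs$on, opp)
  expect_true(r$eligible)
  expect_equal(r$dnds_on, 1, tolerance = 1e-12)
  expect_equal(r$dnds_off, 1, tolerance = 1e-12)
  expect_equal(r$immune_dnds, 1, tolerance = 1e-12)
  # delete half the ON nonsynonymous substitutions: immune dN/dS = 0.5
  idx <- which(subs$on & !subs$syn)
  drop <- idx[seq_len(length(idx) / 2)]
  r2 <- immuneDnds(cons[-drop], subs$on[-drop], opp)
  expect_equal(r2$immune_dnds, length(idx[-seq_len(length(idx) / 2)]) /
                 length(idx), tolerance = 1e-12)
})

test_that("per-sample immune dN/dS derives ON-target status from the regions", {
  sim <- simulateCohort(simConfig(n_patients = 2, mmrd_fraction = 1,
                                  seed = 26))
  mu <- cohortMutations(sim$cohort)
  gr <- GenomicRanges::GRanges(mu$chrom, IRanges::IRanges(mu$pos, mu$pos))
  onFromBed <- IRanges::overlapsAny(gr, immunopeptidomeRegions(sim$cohort))
  expect_identical(onFromBed, sim$truth$mutations$on_target)
  d <- immuneDndsPerSample(sim$cohort)
  expect_true(all(d$eligible))
  expect_true(all(is.finite(d$immune_dnds[d$eligible])))
  # clonal-only reuse
  cl <- classifyClonality(sim$cohort)
  dc <- immuneDndsPerSample(sim$cohort, clonality = cl, stratum = "clonal")
  expect_identical(nrow(dc), nrow(d))
})

test_that("a planted ON-target depletion shifts the estimate accordingly", {
  est <- vapply(c(1, 0.5), function(delta) {
    sim <- simulateCohort(simConfig(n_patients = 3, mmrd_fraction = 1,
                                    adenoma_glands = 0,
                                    on_depletion = delta, seed = 37))
    d <- immuneDndsPerSample(sim$cohort)
    stats::median(d$immune_dnds[d$eligible])
  }, numeric(1))
  expect_gt(est[1], est[2])
  expect_lt(abs(est[1] - 1), 0.25)
})
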