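# Hand-built miniature cohorts for edge-case tests (fixtures are always
# constructed in code).

tinyPatients <- function() {
  data.frame(patient_id = c("P1", "P2"), mmr_status = c("MMRp", "MMRd"),
             hla_alleles = c("hla_a_01_01;hla_a_02_01",
                             "hla_a_01_01;hla_a_03_01"),
             stringsAsFactors = FALSE)
}

tinySamples <- function(glands = 3) {
  ids <- c(paste0("P1_G", seq_len(glands)), paste0("P2_G", seq_len(glands)))
  data.frame(sample_id = ids,
             patient_id = rep(c("P1", "P2"), each = glands),
             tissue = "carcinoma", region = "gland", assay = "wgs_deep",
             purity = 0.7, stringsAsFactors = FALSE)
}

tinyMutation <- function(id, patient, gene = "G0001",
                         consequence = "missense", sbc = 0L,
                         tier = "none", pos = 1000L) {
  data.frame(mutation_id = id, patient_id = patient, chrom = "chr1",
             pos = pos, ref = "C", alt = "T", gene = gene,
             consequence = consequence, context = "ACA>ATA",
             impact = "moderate", strong_binder_count = sbc,
             immunogenicity_tier = tier, stringsAsFactors = FALSE)
}

tinyGenotype <- function(mutation_id, sample_id, vaf = 0.4, depth = 50L) {
  data.frame(mutation_id = mutation_id, sample_id = sample_id,
             present = TRUE, vaf = vaf, depth = depth,
             stringsAsFactors = FALSE)
}

# A minimal valid cohort: one mutation per patient, present everywhere.
tinyCohort <- function(glands = 3) {
  sm <- tinySamples(glands)
  mu <- rbind(tinyMutation("M1", "P1", sbc = 2L),
              tinyMutation("M2", "P2"))
  gt <- rbind(tinyGenotype("M1", sm$sample_id[sm$patient_id == "P1"]),
              tinyGenotype("M2", sm$sample_id[sm$patient_id == "P2"]))
  GlandCohort(tinyPatients(), sm, mu, gt)
}
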