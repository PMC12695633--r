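#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' GlandCohort: multi-gland tumour cohort container
#'
#' Central S4 container for a multi-region (gland-resolved) tumour cohort.
#' Holds the patient, sample, mutation and per-sample genotype tables, plus
#' the optional layers each analysis stage consumes: RNA variant-allele
#' support, HLA allele copy-number/imbalance states, normalised expression
#' matrices (variance-stabilised and TPM-like), the promoter-peak ATAC
#' fold-change matrix and the interval catalogues (ATAC peaks, promoter/TSS
#' intervals, transcription-factor binding sites, immunopeptidome ON-target
#' regions).
#'
#' Coordinate conventions follow the source formats: mutation positions are
#' 1-based (VCF-like); interval slots are \code{GRanges}, imported from and
#' exported to BED (0-based half-open on disk).
#'
#' @slot patients data.frame with columns \code{patient_id}, \code{mmr_status}
#'   (\code{"MMRp"}/\code{"MMRd"}), \code{hla_alleles}
#'   (semicolon-separated class-I alleles).
#' @slot samples data.frame with \code{sample_id}, \code{patient_id},
#'   \code{tissue} (normal/adenoma/carcinoma), \code{region}, \code{assay}
#'   (wgs_deep/wgs_lowpass/panel), \code{purity}.
#' @slot mutations data.frame with \code{mutation_id}, \code{patient_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#'   \code{consequence}, \code{context} (192-class key), \code{impact},
#'   \code{strong_binder_count}, \code{immunogenicity_tier}.
#' @slot genotypes data.frame with \code{mutation_id}, \code{sample_id},
#'   \code{present}, \code{vaf}, \code{depth}.
#' @slot rnaSupport data.frame with \code{mutation_id}, \code{sample_id},
#'   \code{ref_reads}, \code{alt_reads} (may be empty: RNA stages disabled).
#' @slot hlaStates data.frame with \code{patient_id}, \code{sample_id},
#'   \code{allele}, \code{ai_pvalue}, \code{cn_lost}, \code{ci_low},
#'   \code{ci_high}, \code{cn_kept}, \code{mismatch_sites},
#'   \code{minor_allele_cn}, \code{corroborated}.
#' @slot vst numeric matrix, genes x samples (variance-stabilised scale).
#' @slot tpm numeric matrix, genes x samples (TPM-like scale, non-negative).
#' @slot atacFC numeric matrix, peaks x cancers (log2 fold change vs normal).
#' @slot peaks,promoters,tfSites,onRegions \code{GRanges} catalogues (or
#'   \code{NULL} when absent); \code{name} metadata column carries the peak
#'   id, gene symbol or TF symbol.
#' @seealso [readCohort()], [writeCohort()], [simulateCohort()]
#' @export
setClass("GlandCohort",
  representation(
    patients   = "data.frame",
    samples    = "data.frame",
    mutations  = "data.frame",
    genotypes  = "data.frame",
    rnaSupport = "data.frame",
    hlaStates  = "data.frame",
    vst        = "matrix",
    tpm        = "matrix",
    atacFC     = "matrix",
    peaks      = "GRangesOrNULL",
    promoters  = "GRangesOrNULL",
    tfSites    = "GRangesOrNULL",
    onRegions  = "GRangesOrNULL"
  ),
  prototype(
    rnaSupport = data.frame(), hlaStates = data.frame(),
    vst = matrix(numeric(0), 0, 0), tpm = matrix(numeric(0), 0, 0),
    atacFC = matrix(numeric(0), 0, 0),
    peaks = NULL, promoters = NULL, tfSites = NULL, onRegions = NULL
  )
)

.validGlandCohort <- function(object) {
  msg <- character(0)
  pt <- object@patients; sm <- object@samples
  mu <- object@mutations; gt <- object@genotypes

  req <- function(df, cols, tab) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("table '%s' lacks column(s): %s", tab,
                              paste(miss, collapse = ", ")) else NULL
  }
  msg <- c(msg,
    req(pt, c("patient_id", "mmr_status", "hla_alleles"), "patients"),
    req(sm, c("sample_id", "patient_id", "tissue", "assay", "purity"),
        "samples"),
    req(mu, c("mutation_id", "patient_id", "chrom", "pos", "ref", "alt",
              "gene", "consequence", "context", "strong_binder_count"),
        "mutations"),
    req(gt, c("mutation_id", "sample_id", "present", "vaf", "depth"),
        "genotypes"))
  if (length(msg)) return(msg)

  if (anyDuplicated(pt$patient_id))
    msg <- c(msg, "duplicated patient_id in patients table")
  if (anyDuplicated(sm$sample_id))
    msg <- c(msg, "duplicated sample_id in samples table")
  if (!all(sm$patient_id %in% pt$patient_id))
    msg <- c(msg, "referential error: samples reference unknown patient_id")
  if (!all(mu$patient_id %in% pt$patient_id))
    msg <- c(msg, "referential error: mutations reference unknown patient_id")
  if (nrow(gt)) {
    if (!all(gt$mutation_id %in% mu$mutation_id))
      msg <- c(msg, "referential error: genotypes reference unknown mutation_id")
    if (!all(gt$sample_id %in% sm$sample_id))
      msg <- c(msg, "referential error: genotypes reference unknown sample_id")
    bad <- gt$present & (is.na(gt$vaf) | gt$vaf <= 0)
    if (any(bad))
      msg <- c(msg, "genotype rows with present=TRUE must carry vaf > 0")
    if (any(!is.na(gt$vaf) & (gt$vaf < 0 | gt$vaf > 1)))
      msg <- c(msg, "vaf outside [0, 1]")
  }
  ok <- is.na(sm$purity) | (sm$purity >= 0 & sm$purity <= 1)
  if (!all(ok)) msg <- c(msg, "purity outside [0, 1]")
  syn <- mu$consequence == "synonymous" & mu$strong_binder_count > 0
  if (any(syn))
    msg <- c(msg, "synonymous mutations cannot carry strong-binding peptides")
  if (.hasTable(object@rnaSupport)) {
    rs <- object@rnaSupport
    m2 <- req(rs, c("mutation_id", "sample_id", "ref_reads", "alt_reads"),
              "rna_support")
    if (!is.null(m2)) msg <- c(msg, m2)
    else if (any(rs$ref_reads < 0 | rs$alt_reads < 0))
      msg <- c(msg, "negative RNA read counts")
  }
  if (.hasTable(object@hlaStates)) {
    hs <- object@hlaStates
    if (all(c("ci_low", "cn_lost", "ci_high") %in% names(hs))) {
      bad <- !is.na(hs$ci_low) & !is.na(hs$ci_high) &
        (hs$ci_low > hs$cn_lost | hs$cn_lost > hs$ci_high)
      if (any(bad)) msg <- c(msg, "HLA state CI must bracket cn_lost")
    }
  }
  if (.hasMatrix(object@tpm) && any(object@tpm < 0))
    msg <- c(msg, "TPM-like expression values must be non-negative")
  if (length(msg)) msg else TRUE
}

setValidity("GlandCohort", .validGlandCohort)

#' Construct a GlandCohort
#'
#' @param patients,samples,mutations,genotypes required cohort tables
#'   (see the class documentation for columns).
#' @param rnaSupport,hlaStates optional tables; empty data.frame disables the
#'   corresponding stages.
#' @param vst,tpm,atacFC optional matrices.
#' @param peaks,promoters,tfSites,onRegions optional \code{GRanges}.
#' @return A validated [GlandCohort-class] object.
#' @export
GlandCohort <- function(patients, samples, mutations, genotypes,
                        rnaSupport = data.frame(), hlaStates = data.frame(),
                        vst = matrix(numeric(0), 0, 0),
                        tpm = matrix(numeric(0), 0, 0),
                        atacFC = matrix(numeric(0), 0, 0),
                        peaks = NULL, promoters = NULL, tfSites = NULL,
                        onRegions = NULL) {
  new("GlandCohort", patients = as.data.frame(patients),
      samples = as.data.frame(samples), mutations = as.data.frame(mutations),
      genotypes = as.data.frame(genotypes),
      rnaSupport = as.data.frame(rnaSupport),
      hlaStates = as.data.frame(hlaStates),
      vst = vst, tpm = tpm, atacFC = atacFC, peaks = peaks,
      promoters = promoters, tfSites = tfSites, onRegions = onRegions)
}

setMethod("show", "GlandCohort", function(object) {
  cat("GlandCohort object\n")
  cat(sprintf("  %d patients (%d MMRd), %d samples, %d mutations\n",
              nrow(object@patients),
              sum(object@patients$mmr_status == "MMRd"),
              nrow(object@samples), nrow(object@mutations)))
  cat(sprintf("  genotype rows: %d; RNA support: %s; HLA states: %s\n",
              nrow(object@genotypes),
              if (.hasTable(object@rnaSupport)) "yes" else "no",
              if (.hasTable(object@hlaStates)) "yes" else "no"))
  cat(sprintf("  expression: vst %s, tpm %s; ATAC fold-change: %s\n",
              if (.hasMatrix(object@vst))
                paste(dim(object@vst), collapse = "x") else "absent",
              if (.hasMatrix(object@tpm))
                paste(dim(object@tpm), collapse = "x") else "absent",
              if (.hasMatrix(object@atacFC))
                paste(dim(object@atacFC), collapse = "x") else "absent"))
  nint <- function(g) if (is.null(g)) "absent" else as.character(length(g))
  cat(sprintf("  intervals: peaks %s, promoters %s, TF sites %s, ON regions %s\n",
              nint(object@peaks), nint(object@promoters),
              nint(object@tfSites), nint(object@onRegions)))
  invisible(object)
})
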