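#' Antigen-presenting gene (APG) catalogue
#'
#' The curated MHC class-I antigen processing and presentation gene set used
#' for escape calling and chromatin accessibility enrichment (KEGG antigen
#' processing and presentation pathway, class-I arm; 35 symbols).
#'
#' @return Character vector of 35 gene symbols.
#' @examples
#' length(apgGenes())
#' @export
apgGenes <- function() {
  c("TAP1", "TAP2", "IRF1", "NLRC5", "TBK1", "PSME3", "PSME1", "ERAP2",
    "ERAP1", "HSPBP1", "CALR", "B2M", "PSME2", "PSMA7", "CANX", "CIITA",
    "TAPBP", "CREB1", "HLA-A", "HLA-B", "HLA-C", "HSP90AA1", "HSP90AB1",
    "HSPA2", "HSPA4", "HSPA5", "HSPA6", "HSPA8", "IFNG", "NFYA", "NFYB",
    "NFYC", "RFX5", "RFXANK", "RFXAP")
}

.hlaClassI <- function() c("HLA-A", "HLA-B", "HLA-C")
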