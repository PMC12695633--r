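## Readers/writers for the on-disk cohort layout. All tables are headered
## TSV; interval catalogues are BED (0-based half-open on disk, converted by
## rtracklayer); mutation positions stay 1-based in mutations.tsv.

.cohortFiles <- c(
  patients = "patients.tsv", samples = "samples.tsv",
  mutations = "mutations.tsv", genotypes = "genotypes.tsv",
  rna_support = "rna_support.tsv", hla_states = "hla_states.tsv",
  expression_vst = "expression_vst.tsv", expression_tpm = "expression_tpm.tsv",
  atac_fc = "atac_fc.tsv", peaks = "peaks.bed", promoters = "promoters.bed",
  tf_sites = "tf_sites.bed", immunopeptidome = "immunopeptidome.bed")

.readTSV <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeMatrixTSV <- function(m, path, idcol) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idcol
  .writeTSV(df, path)
}

.importBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(GenomicRanges::width(gr) < 1))
    stop("validation error: malformed interval (start >= end) in ", path,
         call. = FALSE)
  gr
}

.resolveManifest <- function(path) {
  if (dir.exists(path)) {
    files <- file.path(path, .cohortFiles)
    names(files) <- names(.cohortFiles)
    return(files)
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML manifest requires the 'yaml' package")
    man <- yaml::read_yaml(path)
    base <- dirname(path)
    files <- vapply(names(.cohortFiles), function(k) {
      p <- man[[k]] %||% NA_character_
      if (is.na(p)) NA_character_
      else if (file.exists(p)) p else file.path(base, p)
    }, character(1))
    return(files)
  }
  stop("manifest must be a cohort directory or a YAML manifest file")
}

#' Read a cohort from disk
#'
#' Loads the full cohort layout (TSV tables plus BED interval catalogues)
#' into a validated [GlandCohort-class]. The four core tables (patients,
#' samples, mutations, genotypes) are required; every other layer is
#' optional and its absence disables the corresponding analysis stages with
#' a warning.
#'
#' @param path Cohort directory (standard file names) or a YAML manifest
#'   mapping table keys (\code{patients}, \code{samples}, \code{mutations},
#'   \code{genotypes}, \code{rna_support}, \code{hla_states},
#'   \code{expression_vst}, \code{expression_tpm}, \code{atac_fc},
#'   \code{peaks}, \code{promoters}, \code{tf_sites},
#'   \code{immunopeptidome}) to file paths.
#' @return A validated [GlandCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path) {
  files <- .resolveManifest(path)
  need <- c("patients", "samples", "mutations", "genotypes")
  for (k in need) {
    if (is.na(files[[k]]) || !file.exists(files[[k]]))
      stop(sprintf("required cohort table '%s' not found", k), call. = FALSE)
  }
  readOpt <- function(k, reader) {
    p <- files[[k]]
    if (is.na(p) || !file.exists(p)) {
      warning(sprintf("optional cohort input '%s' absent; dependent stages disabled", k),
              call. = FALSE)
      return(NULL)
    }
    reader(p)
  }
  pt <- .readTSV(files[["patients"]])
  sm <- .readTSV(files[["samples"]])
  mu <- .readTSV(files[["mutations"]])
  gt <- .readTSV(files[["genotypes"]])
  .assertCols(pt, c("patient_id", "mmr_status", "hla_alleles"), "patients")
  .assertCols(sm, c("sample_id", "patient_id", "tissue", "assay", "purity"),
              "samples")
  .assertCols(mu, c("mutation_id", "patient_id", "chrom", "pos", "ref", "alt",
                    "gene", "consequence", "context", "strong_binder_count"),
              "mutations")
  .assertCols(gt, c("mutation_id", "sample_id", "present", "vaf", "depth"),
              "genotypes")
  gt$present <- as.logical(gt$present)
  rs <- readOpt("rna_support", .readTSV)
  hs <- readOpt("hla_states", .readTSV)
  vst <- readOpt("expression_vst", .readMatrixTSV)
  tpm <- readOpt("expression_tpm", .readMatrixTSV)
  fc <- readOpt("atac_fc", .readMatrixTSV)
  pk <- readOpt("peaks", .importBed)
  pr <- readOpt("promoters", .importBed)
  tf <- readOpt("tf_sites", .importBed)
  on <- readOpt("immunopeptidome", .importBed)
  GlandCohort(pt, sm, mu, gt,
              rnaSupport = rs %||% data.frame(),
              hlaStates = hs %||% data.frame(),
              vst = vst %||% matrix(numeric(0), 0, 0),
              tpm = tpm %||% matrix(numeric(0), 0, 0),
              atacFC = fc %||% matrix(numeric(0), 0, 0),
              peaks = pk, promoters = pr, tfSites = tf, onRegions = on)
}

#' Write a cohort to disk
#'
#' Serialises a [GlandCohort-class] into the standard directory layout
#' consumed by [readCohort()]. Empty optional layers are skipped.
#'
#' @param cohort A [GlandCohort-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "GlandCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTSV(cohort@patients, file.path(dir, "patients.tsv"))
  .writeTSV(cohort@samples, file.path(dir, "samples.tsv"))
  .writeTSV(cohort@mutations, file.path(dir, "mutations.tsv"))
  .writeTSV(cohort@genotypes, file.path(dir, "genotypes.tsv"))
  if (.hasTable(cohort@rnaSupport))
    .writeTSV(cohort@rnaSupport, file.path(dir, "rna_support.tsv"))
  if (.hasTable(cohort@hlaStates))
    .writeTSV(cohort@hlaStates, file.path(dir, "hla_states.tsv"))
  if (.hasMatrix(cohort@vst))
    .writeMatrixTSV(cohort@vst, file.path(dir, "expression_vst.tsv"), "gene")
  if (.hasMatrix(cohort@tpm))
    .writeMatrixTSV(cohort@tpm, file.path(dir, "expression_tpm.tsv"), "gene")
  if (.hasMatrix(cohort@atacFC))
    .writeMatrixTSV(cohort@atacFC, file.path(dir, "atac_fc.tsv"), "peak_id")
  exportBed <- function(gr, file) {
    if (!is.null(gr)) rtracklayer::export(gr, file.path(dir, file),
                                          format = "BED")
  }
  exportBed(cohort@peaks, "peaks.bed")
  exportBed(cohort@promoters, "promoters.bed")
  exportBed(cohort@tfSites, "tf_sites.bed")
  exportBed(cohort@onRegions, "immunopeptidome.bed")
  invisible(dir)
}

#' Validate a cohort on disk
#'
#' Reads and validates a cohort, returning the validated object; errors
#' name the offending column or foreign key.
#'
#' @inheritParams readCohort
#' @return A validated [GlandCohort-class], invisibly.
#' @export
validateCohort <- function(path) {
  invisible(readCohort(path))
}
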