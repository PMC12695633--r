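## Somatic chromatin accessibility alteration (SCAA) analysis: thresholded
## calls from cancer-vs-normal fold changes, promoter assignment, APG
## loss-bias permutation test, neoantigen association and TF proximity.

#' Threshold a log2 accessibility fold change into a SCAA direction
#'
#' @param fold_change Numeric vector of log2 cancer-vs-normal fold changes.
#' @param loss,gain Thresholds: loss below \code{loss} (default -1), gain
#'   above \code{gain} (default 1).
#' @return Character vector: \code{"loss"}, \code{"gain"} or \code{"none"}.
#' @export
callScaa <- function(fold_change, loss = -1, gain = 1) {
  if (any(!is.finite(fold_change)))
    stop("non-finite fold change", call. = FALSE)
  ifelse(fold_change < loss, "loss",
         ifelse(fold_change > gain, "gain", "none"))
}

.tssPoints <- function(promoters) {
  s <- as.character(GenomicRanges::strand(promoters))
  pos <- ifelse(s == "-", GenomicRanges::end(promoters),
                GenomicRanges::start(promoters))
  GenomicRanges::GRanges(GenomicRanges::seqnames(promoters),
                         IRanges::IRanges(pos, pos),
                         name = promoters$name)
}

#' Assign peaks to genes by TSS proximity
#'
#' A peak is assigned to the gene whose strand-resolved transcription start
#' site lies within \code{window} bp (distance 0 when overlapping); the
#' nearest TSS wins, ties broken by the lexicographically smaller gene
#' symbol. Peaks with no TSS in range get an empty assignment.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param promoters \code{GRanges} of promoter intervals with \code{name}
#'   (gene) and strand; the TSS is the 5' end.
#' @param window Maximum TSS distance in bp (default 1000).
#' @return Character vector of gene symbols ("" when unassigned), parallel
#'   to \code{peaks}.
#' @export
assignPromoter <- function(peaks, promoters, window = 1000) {
  tss <- .tssPoints(promoters)
  hits <- GenomicRanges::findOverlaps(peaks, tss, maxgap = window)
  if (!length(hits)) return(rep("", length(peaks)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(peaks[qh], tss[sh])
  keep <- !is.na(d) & d <= window
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  gene <- tss$name[sh]
  out <- rep("", length(peaks))
  ord <- order(qh, d, gene)
  qh <- qh[ord]; gene <- gene[ord]
  first <- !duplicated(qh)
  out[qh[first]] <- gene[first]
  out
}

#' Call SCAAs across a cohort
#'
#' Thresholds the peak x cancer fold-change matrix into loss/gain calls,
#' assigns each peak to its promoter gene and flags recurrent losses
#' (loss of the same peak in more than one patient). Calls are per cancer
#' (clonal by construction); per-sample accessibility is out of scope.
#'
#' @param cohort A [GlandCohort-class] with an ATAC fold-change matrix,
#'   peak and promoter catalogues.
#' @param loss,gain,window Thresholds (see [callScaa()],
#'   [assignPromoter()]).
#' @return data.frame with \code{peak_id}, \code{cancer_id},
#'   \code{fold_change}, \code{direction}, \code{gene},
#'   \code{region_class}, \code{recurrent}.
#' @export
scaaCalls <- function(cohort, loss = -1, gain = 1, window = 1000) {
  fc <- atacFoldChange(cohort)
  if (!.hasMatrix(fc)) stop("cohort carries no ATAC fold-change matrix")
  peaks <- atacPeaks(cohort)
  prom <- promoterRegions(cohort)
  if (is.null(peaks) || is.null(prom))
    stop("SCAA calling needs peak and promoter catalogues")
  gene <- assignPromoter(peaks, prom, window)
  names(gene) <- peaks$name
  long <- data.frame(
    peak_id = rep(rownames(fc), ncol(fc)),
    cancer_id = rep(colnames(fc), each = nrow(fc)),
    fold_change = as.vector(fc), stringsAsFactors = FALSE)
  long$direction <- callScaa(long$fold_change, loss, gain)
  long <- long[long$direction != "none", ]
  long$gene <- unname(gene[long$peak_id])
  long$gene[is.na(long$gene)] <- ""
  long$region_class <- ifelse(long$gene == "", "other", "promoter")
  lossPerPeak <- table(long$peak_id[long$direction == "loss"])
  long$recurrent <- long$direction == "loss" &
    long$peak_id %in% names(lossPerPeak)[lossPerPeak > 1]
  rownames(long) <- NULL
  long
}

#' Permutation test for loss bias in APG accessibility alterations
#'
#' Compares the observed loss fraction among promoter SCAAs of the APG set
#' against random gene sets of uniform-random size drawn from
#' \code{size_range}, using the add-one permutation p-value
#' (k+1)/(n_perm+1). One-sided on losses by default (\code{sided =
#' "loss"}); \code{"two_sided"} scores deviation towards either direction.
#' Random sets without any SCAA have an undefined loss fraction and are
#' counted as not-more-extreme.
#'
#' @param scaa Output of [scaaCalls()] (promoter-assigned rows are used).
#' @param apg APG set (default [apgGenes()]).
#' @param all_genes Gene universe to draw random sets from.
#' @param n_perm Number of random sets (default 200).
#' @param size_range Integer range of random set sizes (default 25--40).
#' @param sided \code{"loss"} or \code{"two_sided"}.
#' @param seed Optional seed fixing the permutations.
#' @return list with \code{observed_loss}, \code{observed_gain},
#'   \code{observed_fraction}, \code{n_permutations},
#'   \code{n_more_extreme}, \code{p_value}, \code{set_sizes}.
#' @export
apgLossBiasTest <- function(scaa, apg = apgGenes(), all_genes,
                            n_perm = 200, size_range = c(25, 40),
                            sided = c("loss", "two_sided"), seed = NULL) {
  sided <- match.arg(sided)
  if (length(all_genes) < max(size_range))
    stop("gene universe smaller than the maximum random set size")
  if (!is.null(seed)) set.seed(seed)
  sc <- scaa[scaa$region_class == "promoter", ]
  stat <- function(genes) {
    s <- sc[sc$gene %in% genes, ]
    nl <- sum(s$direction == "loss"); ng <- sum(s$direction == "gain")
    if (nl + ng == 0) return(NA_real_)
    nl / (nl + ng)
  }
  extremity <- function(f) {
    if (is.na(f)) return(-Inf)
    if (sided == "loss") f else abs(f - 0.5)
  }
  obs <- stat(apg)
  nl <- sum(sc$direction == "loss" & sc$gene %in% apg)
  ng <- sum(sc$direction == "gain" & sc$gene %in% apg)
  sizes <- sample(seq(size_range[1], size_range[2]), n_perm, replace = TRUE)
  perm <- vapply(sizes, function(s) stat(sample(all_genes, s)), numeric(1))
  obsE <- extremity(obs)
  k <- sum(vapply(perm, extremity, numeric(1)) >= obsE - 1e-12)
  list(observed_loss = nl, observed_gain = ng, observed_fraction = obs,
       n_permutations = n_perm, n_more_extreme = k,
       p_value = (k + 1) / (n_perm + 1), set_sizes = sizes)
}

.lossGenesByCancer <- function(scaa) {
  s <- scaa[scaa$direction == "loss" & scaa$region_class == "promoter", ]
  split(s$gene, s$cancer_id)
}

.mutationLossFlags <- function(cohort, scaa, stratum = "all",
                               clonality = NULL) {
  mu <- cohortMutations(cohort)
  keep <- .strataFilter(mu, stratum, clonality)
  mu <- mu[keep & .proteinChanging(mu$consequence), ]
  lg <- .lossGenesByCancer(scaa)
  cancers <- unique(scaa$cancer_id)
  mu <- mu[mu$patient_id %in% cancers, ]
  mu$in_loss <- mapply(function(g, p) g %in% (lg[[p]] %||% character(0)),
                       mu$gene, mu$patient_id)
  mu$neo <- .isNeoantigen(mu$strong_binder_count)
  mu
}

#' Neoantigen x promoter-SCAA-loss association
#'
#' Builds the 2x2 contingency table (neoantigen vs nonantigenic
#' protein-changing mutation x located in a gene with promoter SCAA loss
#' in that cancer vs not) and reports the conditional maximum-likelihood
#' odds ratio with exact CI and two-sided exact p (see [exactOddsRatio()]).
#'
#' @param cohort A [GlandCohort-class].
#' @param scaa Output of [scaaCalls()].
#' @param stratum,clonality Mutation stratum (see [proportionalBurden()]).
#' @return list with \code{table} (2x2 matrix) and the [exactOddsRatio()]
#'   fields.
#' @export
neoantigenScaaAssociation <- function(cohort, scaa, stratum = "all",
                                      clonality = NULL) {
  mu <- .mutationLossFlags(cohort, scaa, stratum, clonality)
  tab <- matrix(c(sum(mu$neo & mu$in_loss), sum(mu$neo & !mu$in_loss),
                  sum(!mu$neo & mu$in_loss), sum(!mu$neo & !mu$in_loss)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("neoantigen", "nonantigenic"),
                                c("scaa_loss", "no_loss")))
  c(list(table = tab), exactOddsRatio(tab))
}

#' Per-cancer paired proportions of mutations downstream of SCAA losses
#'
#' For every cancer, the proportion of neoantigens and of nonantigenic
#' protein-changing mutations lying in promoter-SCAA-loss genes; compared
#' by a two-sided paired Wilcoxon signed-rank test across cancers (exact
#' null for small n, zero differences dropped).
#'
#' @inheritParams neoantigenScaaAssociation
#' @param min_cancers Minimum cancers with both classes (default 3).
#' @return list with \code{per_cancer} data.frame and \code{p_value}.
#' @export
perCancerScaaProportion <- function(cohort, scaa, stratum = "all",
                                    clonality = NULL, min_cancers = 3) {
  mu <- .mutationLossFlags(cohort, scaa, stratum, clonality)
  per <- lapply(split(mu, mu$patient_id), function(d) {
    if (!any(d$neo) || !any(!d$neo)) return(NULL)
    data.frame(cancer_id = d$patient_id[1],
               prop_neoantigen = mean(d$in_loss[d$neo]),
               prop_nonantigenic = mean(d$in_loss[!d$neo]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < min_cancers)
    stop("not evaluable: fewer than ", min_cancers,
         " cancers with both mutation classes", call. = FALSE)
  rownames(per) <- NULL
  p <- .pairedWilcoxon(per$prop_neoantigen, per$prop_nonantigenic)
  list(per_cancer = per, p_value = p)
}

#' TF binding near recurrent APG accessibility losses
#'
#' Counts, per transcription factor, the recurrent APG promoter-loss peaks
#' with a binding site strictly within \code{window} bp; TFs bound to more
#' than \code{min_regions} such regions are selected, and the selected set
#' is tested for enrichment of loss-site binding against the genome-wide
#' peak universe with a one-sided exact test.
#'
#' @param cohort A [GlandCohort-class] with peak and TF site catalogues.
#' @param scaa Output of [scaaCalls()].
#' @param apg APG set restricting the loss regions.
#' @param window Maximum TF site distance (strict, default 1000).
#' @param min_regions Selection cut: bound regions must exceed this.
#' @return list with \code{per_tf} (TF, n_bound_regions, selected),
#'   \code{n_regions}, and \code{enrichment} (exact OR result or NULL).
#' @export
tfLossSiteEnrichment <- function(cohort, scaa, apg = apgGenes(),
                                 window = 1000, min_regions = 2) {
  tf <- tfBindingSites(cohort)
  peaks <- atacPeaks(cohort)
  if (is.null(tf) || length(tf) == 0)
    return(list(per_tf = data.frame(tf = character(0),
                                    n_bound_regions = integer(0),
                                    selected = logical(0)),
                n_regions = 0L, enrichment = NULL))
  rec <- unique(scaa$peak_id[scaa$recurrent & scaa$gene %in% apg])
  if (!length(rec))
    return(list(per_tf = data.frame(tf = character(0),
                                    n_bound_regions = integer(0),
                                    selected = logical(0)),
                n_regions = 0L, enrichment = NULL))
  regions <- peaks[peaks$name %in% rec]
  boundWithin <- function(target) {
    hits <- GenomicRanges::findOverlaps(target, tf, maxgap = window)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(target[qh], tf[sh])
    keep <- !is.na(d) & d < window
    data.frame(region = target$name[qh[keep]], tf = tf$name[sh[keep]])
  }
  hb <- boundWithin(regions)
  tfs <- sort(unique(tf$name))
  nb <- vapply(tfs, function(t) length(unique(hb$region[hb$tf == t])),
               integer(1))
  perTf <- data.frame(tf = tfs, n_bound_regions = nb,
                      selected = nb > min_regions, stringsAsFactors = FALSE)
  sel <- perTf$tf[perTf$selected]
  enr <- NULL
  if (length(sel)) {
    allHits <- boundWithin(peaks)
    boundAny <- unique(allHits$region[allHits$tf %in% sel])
    isRec <- peaks$name %in% rec
    isBound <- peaks$name %in% boundAny
    tab <- matrix(c(sum(isRec & isBound), sum(isRec & !isBound),
                    sum(!isRec & isBound), sum(!isRec & !isBound)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("loss_region", "other_peak"),
                                  c("bound", "unbound")))
    enr <- c(list(table = tab), exactOddsRatio(tab, sided = "greater"))
  }
  list(per_tf = perTf, n_regions = length(rec), enrichment = enr)
}
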