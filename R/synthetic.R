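## Synthetic multi-gland cohort generator. Every downstream stage has a
## planted, recoverable ground truth; defaults emulate the cohort-scale
## regimes of mismatch-repair proficient/deficient colorectal cancers
## (hypermutant vs non-hypermutant burden, clonal sharing across glands,
## promoter accessibility loss biased towards antigen-presenting genes,
## allele-specific silencing of neoantigens, VAF depletion of immunogenic
## subclones).

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by [simulateCohort()].
#' Defaults describe the study conditions the package targets; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_patients Number of patients (cancers).
#' @param glands_per_patient Deep-sequenced carcinoma glands per patient.
#' @param adenoma_glands Adenoma glands per patient (0 disables adenomas).
#' @param mmrd_fraction Fraction of patients that are mismatch-repair
#'   deficient (hypermutant).
#' @param mut_mean_mmrp,mut_mean_mmrd Negative-binomial mean coding-mutation
#'   count per MMRp / MMRd cancer (size \code{mut_size}). Defaults put the
#'   median synonymous burden near 18 and 307 respectively.
#' @param mut_size Negative-binomial size (dispersion) for mutation counts.
#' @param adenoma_mut_mean Mean mutation count of the adenoma-private pool.
#' @param clonal_fraction Probability a carcinoma mutation is clonal
#'   (present in every gland).
#' @param neoantigen_rate Probability a protein-changing carcinoma mutation
#'   yields at least one strong-binding peptide.
#' @param neoantigen_rate_adenoma Same, for adenoma-private mutations.
#' @param high_tier_rate Fraction of neoantigens labelled high
#'   immunogenicity.
#' @param silencing_or Planted odds ratio that a neoantigen (vs nonantigenic
#'   mutation) is transcriptionally silenced (allele dropout in RNA).
#' @param silencing_base Baseline silencing probability for nonantigenic
#'   mutations.
#' @param scaa_event_rate_apg,scaa_event_rate_background Per-gene-per-cancer
#'   probability of a promoter accessibility alteration for APGs vs
#'   background genes.
#' @param scaa_loss_rate_apg,scaa_loss_rate_background Probability that such
#'   an alteration is a loss (vs gain).
#' @param scaa_neo_or Planted odds ratio that a neoantigen lies in a gene
#'   whose promoter carries an accessibility loss in that cancer.
#' @param vaf_depletion_effect Fractional down-shift applied to the VAF of
#'   subclonal high-immunogenicity neoantigens (0 = no depletion).
#' @param rna_depth_mean,rna_depth_size Negative-binomial RNA depth per
#'   mutation-sample pair.
#' @param atac_noise_sd Gaussian noise SD on log2 ATAC fold changes.
#' @param on_fraction Fraction of each gene body covered by the
#'   immunopeptidome (ON-target) region.
#' @param on_depletion Multiplier on the ON-target nonsynonymous rate; the
#'   planted immune dN/dS (1 = neutral, 0.5 = 50\% depletion).
#' @param n_genes Size of the gene universe (includes the 35 APGs).
#' @param escape_plan Either \code{NULL} (sample per-patient escape classes
#'   from \code{escape_probs}) or a character vector of length
#'   \code{n_patients} with values in \code{clonal}, \code{subclonal},
#'   \code{minor_subclonal}, \code{none}.
#' @param escape_probs Sampling probabilities for the escape classes when
#'   \code{escape_plan} is \code{NULL}.
#' @param spectrum Optional named vector of relative rates over the 192
#'   trinucleotide classes (default uniform).
#' @param seed Integer seed fixing the full output.
#' @return A validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_patients = 8,
                      glands_per_patient = 5,
                      adenoma_glands = 2,
                      mmrd_fraction = 0.2,
                      mut_mean_mmrp = 80,
                      mut_mean_mmrd = 1340,
                      mut_size = 12,
                      adenoma_mut_mean = 60,
                      clonal_fraction = 0.6,
                      neoantigen_rate = 0.3,
                      neoantigen_rate_adenoma = 0.18,
                      high_tier_rate = 0.3,
                      silencing_or = 1.5,
                      silencing_base = 0.15,
                      scaa_event_rate_apg = 0.05,
                      scaa_event_rate_background = 0.04,
                      scaa_loss_rate_apg = 0.93,
                      scaa_loss_rate_background = 0.5,
                      scaa_neo_or = 1.5,
                      vaf_depletion_effect = 0.5,
                      rna_depth_mean = 20,
                      rna_depth_size = 5,
                      atac_noise_sd = 0.25,
                      on_fraction = 0.15,
                      on_depletion = 1,
                      n_genes = 400,
                      escape_plan = NULL,
                      escape_probs = c(clonal = 0.28, subclonal = 0.07,
                                       minor_subclonal = 0.14, none = 0.51),
                      spectrum = NULL,
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  if (n_patients < 1 || glands_per_patient < 1)
    stop("config error: need at least 1 patient and 1 gland", call. = FALSE)
  for (p in c("mmrd_fraction", "clonal_fraction", "neoantigen_rate",
              "neoantigen_rate_adenoma", "high_tier_rate", "silencing_base",
              "scaa_event_rate_apg", "scaa_event_rate_background",
              "scaa_loss_rate_apg", "scaa_loss_rate_background",
              "vaf_depletion_effect", "on_fraction"))
    .assertProb(cfg[[p]], p)
  if (silencing_or < 0) stop("config error: silencing_or must be >= 0")
  if (scaa_neo_or < 0) stop("config error: scaa_neo_or must be >= 0")
  if (!is.null(escape_plan)) {
    if (length(escape_plan) != n_patients)
      stop("config error: escape_plan must have one entry per patient")
    bad <- setdiff(escape_plan,
                   c("clonal", "subclonal", "minor_subclonal", "none"))
    if (length(bad)) stop("config error: unknown escape class ", bad[1])
  }
  if (!is.null(spectrum)) {
    if (!all(trinucContexts() %in% names(spectrum)))
      stop("config error: spectrum must cover all 192 contexts")
  }
  if (n_genes <= 45) stop("config error: gene universe too small")
  cfg
}

## Gene universe geometry (positions on a synthetic chromosome).
.geneTable <- function(cfg) {
  apg <- apgGenes()
  n_bg <- cfg$n_genes - length(apg)
  genes <- c(apg, sprintf("G%04d", seq_len(n_bg)))
  n <- length(genes)
  glen <- 3000L
  start <- (seq_len(n) - 1L) * 20000L + 1L
  strand <- rep(c("+", "-"), length.out = n)
  tss <- ifelse(strand == "+", start, start + glen - 1L)
  data.frame(gene = genes, chrom = "chr1", start = start,
             end = start + glen - 1L, strand = strand, tss = tss,
             apg = genes %in% apg, stringsAsFactors = FALSE)
}

.hlaAllelePool <- function() {
  list(A = sprintf("hla_a_%02d_01", 1:12),
       B = sprintf("hla_b_%02d_01", 1:12),
       C = sprintf("hla_c_%02d_01", 1:12))
}

## SNV (region, class) sampling weights given the opportunity geometry and a
## planted ON-target nonsynonymous depletion delta.
.snvWeights <- function(on_fraction, delta) {
  w <- c(off_syn = 0.25 * (1 - on_fraction),
         off_non = 0.75 * (1 - on_fraction),
         on_syn  = 0.25 * on_fraction,
         on_non  = 0.75 * on_fraction * delta)
  w / sum(w)
}

.sampleContexts <- function(n, spectrum) {
  ctx <- trinucContexts()
  if (is.null(spectrum)) sample(ctx, n, replace = TRUE)
  else sample(ctx, n, replace = TRUE, prob = spectrum[ctx])
}

#' Simulate a multi-gland cohort with planted ground truth
#'
#' Generates a full [GlandCohort-class] (all tables, expression matrices,
#' ATAC fold changes and interval catalogues) together with the planted
#' ground truth for every analysis stage. Clonal mutations are present in
#' all carcinoma glands of a patient; subclonal mutations follow a nested
#' subclone scheme (2--4 nested subclones over random gland subsets).
#' Output is fully determined by \code{config$seed}.
#'
#' @param config A [simConfig()].
#' @return A list with elements \code{cohort} ([GlandCohort-class]) and
#'   \code{truth} (list of data.frames: \code{mutations}, \code{samples},
#'   \code{patients}, \code{scaa}).
#' @examples
#' sim <- simulateCohort(simConfig(n_patients = 2, seed = 7))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  set.seed(cfg$seed)
  gt <- .geneTable(cfg)
  pool <- .hlaAllelePool()
  G <- cfg$glands_per_patient
  nA <- cfg$adenoma_glands

  n_mmrd <- round(cfg$n_patients * cfg$mmrd_fraction)
  pid <- sprintf("C%03d", 500 + seq_len(cfg$n_patients))
  mmr <- rep("MMRp", cfg$n_patients)
  if (n_mmrd > 0) mmr[sample(cfg$n_patients, n_mmrd)] <- "MMRd"
  hla <- vapply(seq_len(cfg$n_patients), function(i) {
    paste(c(sample(pool$A, 2), sample(pool$B, 2), sample(pool$C, 2)),
          collapse = ";")
  }, character(1))
  patients <- data.frame(patient_id = pid, mmr_status = mmr,
                         hla_alleles = hla, stringsAsFactors = FALSE)

  ## escape plan: hypermutant cancers always carry clonal escape
  plan <- cfg$escape_plan
  if (is.null(plan)) {
    plan <- sample(names(cfg$escape_probs), cfg$n_patients, replace = TRUE,
                   prob = cfg$escape_probs)
    plan[mmr == "MMRd"] <- "clonal"
  }
  mech_pool <- c("hla_loh", "hla_frameshift", "hla_stopgain",
                 "apg_high_impact", "checkpoint")
  mech <- ifelse(plan == "none", "none",
                 sample(mech_pool, cfg$n_patients, replace = TRUE))

  ## samples
  sampleRows <- list(); k <- 1L
  for (i in seq_len(cfg$n_patients)) {
    ids <- c(sprintf("%s_G%d", pid[i], seq_len(G)),
             if (nA > 0) sprintf("%s_A%d", pid[i], seq_len(nA)),
             sprintf("%s_N1", pid[i]))
    tissue <- c(rep("carcinoma", G), rep("adenoma", nA), "normal")
    region <- c(rep("gland", G + nA), "normal_mucosa")
    purity <- c(round(runif(G + nA, 0.5, 0.95), 3), 0)
    sampleRows[[k]] <- data.frame(sample_id = ids, patient_id = pid[i],
                                  tissue = tissue, region = region,
                                  assay = "wgs_deep", purity = purity,
                                  stringsAsFactors = FALSE)
    k <- k + 1L
  }
  samples <- do.call(rbind, sampleRows)

  ## planted SCAA events (per cancer x gene)
  scaaRows <- list(); k <- 1L
  lossGenes <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    rate <- ifelse(gt$apg, cfg$scaa_event_rate_apg,
                   cfg$scaa_event_rate_background)
    hit <- runif(nrow(gt)) < rate
    if (!any(hit)) { lossGenes[[i]] <- character(0); next }
    lossp <- ifelse(gt$apg[hit], cfg$scaa_loss_rate_apg,
                    cfg$scaa_loss_rate_background)
    dirn <- ifelse(runif(sum(hit)) < lossp, "loss", "gain")
    scaaRows[[k]] <- data.frame(patient_id = pid[i], gene = gt$gene[hit],
                                direction = dirn, stringsAsFactors = FALSE)
    lossGenes[[i]] <- gt$gene[hit][dirn == "loss"]
    k <- k + 1L
  }
  truthScaa <- if (length(scaaRows)) do.call(rbind, scaaRows) else
    data.frame(patient_id = character(0), gene = character(0),
               direction = character(0))

  onLen <- round(cfg$on_fraction * 3000)
  ctxAll <- trinucContexts()

  mutRows <- list(); genoRows <- list(); truthMutRows <- list()
  escMutRows <- list()
  hlaRows <- list()
  escGlands <- vector("list", cfg$n_patients)
  mi <- 1L

  drawSnvClass <- function(n, delta) {
    w <- .snvWeights(cfg$on_fraction, delta)
    cls <- sample(names(w), n, replace = TRUE, prob = w)
    list(on = grepl("^on", cls), syn = grepl("syn$", cls))
  }

  makeMutations <- function(patient, n, neo_rate, delta) {
    is_fs <- runif(n) < 0.08
    cls <- drawSnvClass(n, delta)
    on <- ifelse(is_fs, runif(n) < cfg$on_fraction, cls$on)
    syn <- !is_fs & cls$syn
    consequence <- character(n)
    consequence[syn] <- "synonymous"
    nonsyn <- !is_fs & !syn
    consequence[nonsyn] <- sample(c("missense", "nonsense", "splice"),
                                  sum(nonsyn), replace = TRUE,
                                  prob = c(0.88, 0.07, 0.05))
    consequence[is_fs] <- "frameshift"
    pc <- .proteinChanging(consequence)
    neo <- pc & runif(n) < neo_rate
    sbc <- ifelse(neo, 1L + rpois(n, 1.2), 0L)
    tier <- ifelse(neo, ifelse(runif(n) < cfg$high_tier_rate, "high", "low"),
                   "none")
    impact <- ifelse(consequence %in% c("frameshift", "nonsense", "splice"),
                     "high",
                     ifelse(consequence == "missense",
                            ifelse(runif(n) < 0.85, "moderate", "low"),
                            "low"))
    ## silencing: planted odds ratio for neoantigens
    b <- cfg$silencing_base / (1 - cfg$silencing_base)
    p_neo <- cfg$silencing_or * b / (1 + cfg$silencing_or * b)
    silenced <- runif(n) < ifelse(neo, p_neo, cfg$silencing_base)
    ## gene assignment with planted neoantigen-in-SCAA-loss-gene odds
    ## ratio; the background pool excludes APGs so that escape-grade
    ## APG/HLA alterations arise only from the escape plan (mirroring the
    ## mutual exclusivity of accessibility losses and APG mutations)
    bg <- gt$gene[!gt$apg]
    lg <- intersect(lossGenes[[match(patient, pid)]], bg)
    gene <- character(n)
    if (length(lg) && length(lg) < length(bg)) {
      q0 <- length(lg) / length(bg)
      odds1 <- cfg$scaa_neo_or * q0 / (1 - q0)
      q1 <- odds1 / (1 + odds1)
      inloss <- runif(n) < ifelse(neo, q1, q0)
      gene[inloss] <- sample(lg, sum(inloss), replace = TRUE)
      gene[!inloss] <- sample(setdiff(bg, lg), sum(!inloss),
                              replace = TRUE)
    } else {
      gene <- sample(bg, n, replace = TRUE)
    }
    gi <- match(gene, gt$gene)
    off <- ifelse(on, floor(runif(n) * onLen),
                  onLen + floor(runif(n) * (3000 - onLen)))
    pos <- gt$start[gi] + as.integer(off)
    ctx <- .sampleContexts(n, cfg$spectrum)
    ref <- substr(ctx, 2, 2)
    alt <- substr(ctx, 6, 6)
    alt[is_fs] <- paste0(ref[is_fs], "A")
    data.frame(gene = gene, chrom = "chr1", pos = pos, ref = ref, alt = alt,
               consequence = consequence, context = ctx, impact = impact,
               strong_binder_count = sbc, immunogenicity_tier = tier,
               on_target = on, silenced = silenced, stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_patients)) {
    mu <- if (mmr[i] == "MMRd") cfg$mut_mean_mmrd else cfg$mut_mean_mmrp
    n <- max(30L, rnbinom(1, mu = mu, size = cfg$mut_size))
    mm <- makeMutations(pid[i], n, cfg$neoantigen_rate, cfg$on_depletion)
    mm$mutation_id <- sprintf("%s_M%05d", pid[i], seq_len(n))
    mm$patient_id <- pid[i]

    ## clonality: nested subclones over gland subsets
    glands <- sprintf("%s_G%d", pid[i], seq_len(G))
    clonal <- runif(n) < cfg$clonal_fraction
    if (G == 1) clonal[] <- TRUE
    memb <- vector("list", n)
    memb[clonal] <- list(glands)
    if (any(!clonal)) {
      nsub <- sample(2:4, 1)
      perm <- sample(glands)
      sizes <- sort(sample(seq_len(max(1, G - 1)), nsub, replace = TRUE),
                    decreasing = TRUE)
      subsets <- lapply(sizes, function(s) perm[seq_len(s)])
      assign <- sample.int(nsub, sum(!clonal), replace = TRUE)
      memb[!clonal] <- subsets[assign]
    }
    mm$truth_clonality <- ifelse(clonal, "clonal", "subclonal")

    ## escape-mechanism extras
    eg <- character(0)
    if (plan[i] != "none") {
      kmin <- ceiling(0.25 * G)
      kk <- switch(plan[i],
        clonal = G,
        subclonal = if (G - 1 >= kmin) sample(seq(kmin, G - 1), 1) else G - 1,
        minor_subclonal = if (kmin > 1) sample(seq_len(kmin - 1), 1) else 1L)
      eg <- sample(glands, kk)
      escGlands[[i]] <- eg
      if (mech[i] %in% c("hla_frameshift", "hla_stopgain",
                         "apg_high_impact")) {
        ## planted APG hits avoid the deliberately silent APGs (IFNG,
        ## HSPA6), which the expression filter removes from eligibility
        gsym <- if (mech[i] == "apg_high_impact")
          sample(setdiff(apgGenes(), c(.hlaClassI(), "IFNG", "HSPA6")), 1)
        else sample(.hlaClassI(), 1)
        cons <- switch(mech[i], hla_frameshift = "frameshift",
                       hla_stopgain = "nonsense",
                       apg_high_impact = "frameshift")
        gi <- match(gsym, gt$gene)
        em <- data.frame(
          gene = gsym, chrom = "chr1",
          pos = gt$start[gi] + onLen + 10L, ref = "C",
          alt = if (cons == "frameshift") "CA" else "A",
          consequence = cons, context = "ACA>AAA", impact = "high",
          strong_binder_count = 0L, immunogenicity_tier = "none",
          on_target = FALSE, silenced = FALSE,
          mutation_id = sprintf("%s_ESC1", pid[i]), patient_id = pid[i],
          truth_clonality = if (kk == G) "clonal" else "subclonal",
          stringsAsFactors = FALSE)
        mm <- rbind(mm, em)
        memb <- c(memb, list(eg))
      }
    }

    ## genotypes: only rows where the mutation is present
    nmut <- nrow(mm)
    reps <- lengths(memb)
    gmut <- rep(mm$mutation_id, reps)
    gsam <- unlist(memb, use.names = FALSE)
    isClon <- rep(mm$truth_clonality == "clonal", reps)
    vaf <- numeric(length(gmut))
    vaf[isClon] <- runif(sum(isClon), 0.30, 0.50)
    vaf[!isClon] <- 0.02 + rbeta(sum(!isClon), 2, 18) * 0.26
    hiTier <- rep(mm$immunogenicity_tier == "high", reps)
    dep <- hiTier & !isClon
    vaf[dep] <- vaf[dep] * (1 - cfg$vaf_depletion_effect)
    depth <- rnbinom(length(gmut), mu = 60, size = 10) + 15L
    vaf <- pmax(vaf, 1.5 / depth)
    genoRows[[i]] <- data.frame(mutation_id = gmut, sample_id = gsam,
                                present = TRUE, vaf = round(vaf, 4),
                                depth = as.integer(depth),
                                stringsAsFactors = FALSE)

    ## adenoma-private pool: clonal within the adenoma glands
    if (nA > 0) {
      na_mut <- max(10L, rnbinom(1, mu = cfg$adenoma_mut_mean,
                                 size = cfg$mut_size))
      am <- makeMutations(pid[i], na_mut, cfg$neoantigen_rate_adenoma, 1)
      am$mutation_id <- sprintf("%s_A%05d", pid[i], seq_len(na_mut))
      am$patient_id <- pid[i]
      am$truth_clonality <- "adenoma"
      aglands <- sprintf("%s_A%d", pid[i], seq_len(nA))
      ## adenoma glands carry their own clonal/subclonal structure
      aclon <- runif(na_mut) < cfg$clonal_fraction
      if (nA == 1) aclon[] <- TRUE
      amemb <- vector("list", na_mut)
      amemb[aclon] <- list(aglands)
      if (any(!aclon)) {
        asz <- sample(seq_len(max(1, nA - 1)), sum(!aclon), replace = TRUE)
        amemb[!aclon] <- lapply(asz, function(s) sample(aglands, s))
      }
      areps <- lengths(amemb)
      amut <- rep(am$mutation_id, areps)
      asam <- unlist(amemb, use.names = FALSE)
      avaf <- numeric(length(amut))
      aIsC <- rep(aclon, areps)
      avaf[aIsC] <- runif(sum(aIsC), 0.30, 0.50)
      avaf[!aIsC] <- 0.02 + rbeta(sum(!aIsC), 2, 18) * 0.26
      adep <- rnbinom(length(amut), mu = 60, size = 10) + 15L
      avaf <- pmax(avaf, 1.5 / adep)
      genoRows[[i]] <- rbind(genoRows[[i]], data.frame(
        mutation_id = amut, sample_id = asam, present = TRUE,
        vaf = round(avaf, 4), depth = as.integer(adep),
        stringsAsFactors = FALSE))
      mm <- rbind(mm, am)
    }
    mutRows[[i]] <- mm
  }

  mutAll <- do.call(rbind, mutRows)
  truthMut <- mutAll[, c("mutation_id", "patient_id", "truth_clonality",
                         "silenced", "on_target", "immunogenicity_tier")]
  names(truthMut)[3] <- "clonality"
  truthMut$neoantigen <- mutAll$strong_binder_count >= 1L
  mutations <- mutAll[, c("mutation_id", "patient_id", "chrom", "pos", "ref",
                          "alt", "gene", "consequence", "context", "impact",
                          "strong_binder_count", "immunogenicity_tier")]
  rownames(mutations) <- NULL
  genotypes <- do.call(rbind, genoRows)
  rownames(genotypes) <- NULL

  ## HLA allele states (LOHHLA/sequenza-like evidence per gland)
  for (i in seq_len(cfg$n_patients)) {
    glands <- sprintf("%s_G%d", pid[i], seq_len(G))
    allele <- strsplit(patients$hla_alleles[i], ";")[[1]][1]
    isLoh <- mech[i] == "hla_loh" & glands %in% (escGlands[[i]] %||%
                                                   character(0))
    cn_lost <- ifelse(isLoh, 0.25, round(runif(G, 0.85, 1.15), 2))
    hlaRows[[i]] <- data.frame(
      patient_id = pid[i], sample_id = glands, allele = allele,
      ai_pvalue = ifelse(isLoh, 0.001, round(runif(G, 0.05, 1), 3)),
      cn_lost = cn_lost,
      ci_low = round(cn_lost - ifelse(isLoh, 0.15, 0.1), 2),
      ci_high = round(cn_lost + ifelse(isLoh, 0.2, 0.1), 2),
      cn_kept = ifelse(isLoh, 1.0, round(runif(G, 0.9, 1.1), 2)),
      mismatch_sites = sample(11:25, G, replace = TRUE),
      minor_allele_cn = ifelse(isLoh, 0L, 1L),
      corroborated = isLoh, stringsAsFactors = FALSE)
  }
  hlaStates <- do.call(rbind, hlaRows)
  rownames(hlaStates) <- NULL

  ## expression matrices
  allSam <- samples$sample_id
  normals <- samples$sample_id[samples$tissue == "normal"]
  tumors <- setdiff(allSam, normals)
  exprGenes <- c(gt$gene, "CD274", "CTLA4")
  nv <- length(exprGenes)
  vst <- matrix(round(rnorm(nv * length(allSam), mean = 8, sd = 0.5), 3),
                nrow = nv, dimnames = list(exprGenes, allSam))
  base <- rnorm(nv, 0, 1.5)
  vst <- round(vst + base, 3)
  ## checkpoint genes: normals standardised to mean 6 / sd 0.4 so that tier
  ## calls are exact on synthetic data; planted overexpression sits at +5 SD
  for (g in c("CD274", "CTLA4")) {
    z <- rnorm(length(normals))
    z <- (z - mean(z)) / stats::sd(z)
    vst[g, normals] <- round(6 + 0.4 * z, 4)
    vst[g, tumors] <- 6
  }
  for (i in seq_len(cfg$n_patients)) {
    if (mech[i] == "checkpoint") {
      vst[c("CD274", "CTLA4"), escGlands[[i]]] <- 8
    }
  }
  tpmBase <- ifelse(exprGenes %in% apgGenes(), 50,
                    exp(rnorm(nv, log(20), 1)))
  tpmBase[exprGenes %in% c("IFNG", "HSPA6")] <- 0.5  # lowly expressed APGs
  tpm <- matrix(round(tpmBase * exp(rnorm(nv * length(allSam), 0, 0.3)), 2),
                nrow = nv, dimnames = list(exprGenes, allSam))

  ## interval catalogues
  mkGR <- function(start, end, name, strand = "*") {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                           strand = strand, name = name)
  }
  promoters <- mkGR(gt$tss - 500L, gt$tss + 499L, gt$gene, gt$strand)
  peakStart <- gt$tss - 300L
  peaks <- mkGR(peakStart, gt$tss + 299L, paste0("pk_", gt$gene))
  nDistal <- 50L
  maxPos <- max(gt$end) + 50000L
  dStart <- maxPos + (seq_len(nDistal)) * 5000L
  distal <- mkGR(dStart, dStart + 599L, sprintf("pk_distal%02d",
                                                seq_len(nDistal)))
  peaks <- c(peaks, distal)
  onRegions <- mkGR(gt$start, gt$start + onLen - 1L, gt$gene)
  tfs <- sprintf("TF%02d", 1:25)
  tfRows <- list()
  for (t in seq_along(tfs)) {
    p <- if (t <= 5) ifelse(gt$apg, 0.6, 0.1) else rep(0.1, nrow(gt))
    hit <- runif(nrow(gt)) < p
    if (!any(hit)) next
    s <- gt$tss[hit] + sample(-800:790, sum(hit), replace = TRUE)
    tfRows[[t]] <- data.frame(start = s, name = tfs[t])
  }
  tfdf <- do.call(rbind, tfRows)
  tfSites <- mkGR(tfdf$start, tfdf$start + 9L, tfdf$name)

  ## ATAC fold-change matrix (peaks x cancers)
  fc <- matrix(round(rnorm(length(peaks) * cfg$n_patients, 0,
                           cfg$atac_noise_sd), 3),
               nrow = length(peaks),
               dimnames = list(peaks$name, pid))
  if (nrow(truthScaa)) {
    for (r in seq_len(nrow(truthScaa))) {
      pk <- paste0("pk_", truthScaa$gene[r])
      sgn <- if (truthScaa$direction[r] == "loss") -1 else 1
      fc[pk, truthScaa$patient_id[r]] <-
        round(sgn * (1.5 + abs(rnorm(1, 0, 0.3))), 3)
    }
  }

  ## RNA support: all present mutation-sample pairs in glandular samples
  rnaIdx <- genotypes$sample_id %in%
    samples$sample_id[samples$tissue != "normal"]
  rg <- genotypes[rnaIdx, c("mutation_id", "sample_id", "vaf")]
  sil <- mutAll$silenced[match(rg$mutation_id, mutAll$mutation_id)]
  rdepth <- rnbinom(nrow(rg), mu = cfg$rna_depth_mean,
                    size = cfg$rna_depth_size)
  ralt <- ifelse(sil, 0L, rbinom(nrow(rg), rdepth, rg$vaf))
  rnaSupport <- data.frame(mutation_id = rg$mutation_id,
                           sample_id = rg$sample_id,
                           ref_reads = as.integer(rdepth - ralt),
                           alt_reads = as.integer(ralt),
                           stringsAsFactors = FALSE)
  rownames(rnaSupport) <- NULL

  ## ground truth bundles
  escLabel <- rep("none", nrow(samples))
  names(escLabel) <- samples$sample_id
  for (i in seq_len(cfg$n_patients)) {
    if (plan[i] != "none")
      escLabel[escGlands[[i]]] <- "escaped"
  }
  truthSamples <- data.frame(sample_id = samples$sample_id,
                             patient_id = samples$patient_id,
                             escape_label = unname(escLabel),
                             stringsAsFactors = FALSE)
  truthPatients <- data.frame(patient_id = pid, mmr_status = mmr,
                              escape_class = plan, mechanism = mech,
                              on_depletion = cfg$on_depletion,
                              silencing_or = cfg$silencing_or,
                              stringsAsFactors = FALSE)

  cohort <- GlandCohort(patients, samples, mutations, genotypes,
                        rnaSupport = rnaSupport, hlaStates = hlaStates,
                        vst = vst, tpm = tpm, atacFC = fc, peaks = peaks,
                        promoters = promoters, tfSites = tfSites,
                        onRegions = onRegions)
  list(cohort = cohort,
       truth = list(mutations = truthMut, samples = truthSamples,
                    patients = truthPatients, scaa = truthScaa))
}

#' Simulate a fully neutral (null) cohort
#'
#' Applies the neutral overrides (silencing odds ratio 1, no escape, equal
#' promoter loss/gain rates for APGs and background, no VAF depletion,
#' neutral immune dN/dS) and simulates; downstream tests on such cohorts
#' should be calibrated (type-I error near nominal, estimates centred on
#' their null values).
#'
#' @param config A [simConfig()]; its planted-effect fields are overridden.
#' @return As [simulateCohort()].
#' @export
simulateNullCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  config$silencing_or <- 1
  config$scaa_neo_or <- 1
  config$scaa_loss_rate_apg <- 0.5
  config$scaa_loss_rate_background <- 0.5
  config$scaa_event_rate_apg <- config$scaa_event_rate_background
  config$vaf_depletion_effect <- 0
  config$on_depletion <- 1
  config$escape_plan <- rep("none", config$n_patients)
  simulateCohort(config)
}
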