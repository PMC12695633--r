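## Shared statistical engines: exact conditional 2x2 association, VAF
## depletion tests, patient-random-effect likelihood-ratio contract and
## multivariable proportion regression.

#' Exact conditional odds ratio for a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio under the noncentral
#' hypergeometric likelihood (conditioning on both margins), exact
#' confidence interval by test inversion and exact p-value. The two-sided
#' p sums the null hypergeometric probabilities not exceeding that of the
#' observed table. Tables with an empty row or column margin carry an
#' undefined odds ratio and p = 1.
#'
#' @param table 2x2 matrix (or vector a,b,c,d in row order) of
#'   non-negative counts; rows are the exposure classes, columns the
#'   outcome classes.
#' @param sided \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @param conf_level Confidence level (default 0.95).
#' @return list with \code{or} (conditional MLE; \code{Inf}/0 at the
#'   support boundary, \code{NA} when undefined), \code{ci_low},
#'   \code{ci_high}, \code{p_value}.
#' @examples
#' exactOddsRatio(matrix(c(10, 20, 5, 40), 2, byrow = TRUE))
#' @export
exactOddsRatio <- function(table, sided = c("two_sided", "greater", "less"),
                           conf_level = 0.95) {
  sided <- match.arg(sided)
  x <- as.vector(t(as.matrix(table)))
  stopifnot(length(x) == 4, all(x >= 0), all(x == round(x)))
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m1 <- a + b; m2 <- cc + d; k <- a + cc; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == N) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = 1))
  }
  lo <- max(0, k - m2); hi <- min(k, m1)
  supp <- lo:hi
  logdc <- lchoose(m1, supp) + lchoose(m2, k - supp)
  dens <- function(t) {          # conditional density at log-odds-ratio t
    w <- logdc + supp * t
    w <- exp(w - max(w))
    w / sum(w)
  }
  meanX <- function(t) sum(supp * dens(t))
  pG <- function(t) sum(dens(t)[supp >= a])
  pL <- function(t) sum(dens(t)[supp <= a])
  solve1 <- function(f, target) {
    g <- function(t) f(t) - target
    lo_t <- -1; hi_t <- 1
    while (g(lo_t) * g(hi_t) > 0 && hi_t < 724) {
      lo_t <- lo_t * 2; hi_t <- hi_t * 2
    }
    stats::uniroot(g, c(lo_t, hi_t), tol = 1e-10)$root
  }
  or <- if (a == lo) 0 else if (a == hi) Inf else exp(solve1(meanX, a))
  d0 <- dens(0)
  p <- switch(sided,
    two_sided = sum(d0[d0 <= d0[supp == a] * (1 + 1e-7)]),
    greater = pG(0),
    less = pL(0))
  alpha <- (1 - conf_level) / 2
  if (sided == "two_sided") {
    ci_low <- if (a == lo) 0 else exp(solve1(pG, alpha))
    ci_high <- if (a == hi) Inf else exp(solve1(pL, alpha))
  } else if (sided == "greater") {
    ci_low <- if (a == lo) 0 else exp(solve1(pG, 1 - conf_level))
    ci_high <- Inf
  } else {
    ci_low <- 0
    ci_high <- if (a == hi) Inf else exp(solve1(pL, 1 - conf_level))
  }
  list(or = or, ci_low = ci_low, ci_high = ci_high,
       p_value = min(1, p))
}

## Paired Wilcoxon signed-rank p: exact null for small n without ties,
## normal approximation with continuity correction otherwise; zero
## differences dropped (signed-rank convention). All-zero differences
## give p = 1.
.pairedWilcoxon <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) return(1)
  ex <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(stats::wilcox.test(d, exact = ex,
                                      correct = TRUE)$p.value)
}

#' Kolmogorov-Smirnov test for VAF depletion of neoantigens
#'
#' Two-sample KS test with the one-sided alternative that neoantigen VAFs
#' are stochastically smaller than those of other mutations (their
#' empirical CDF lies above); two-sided behaviour is available via
#' \code{alternative}.
#'
#' @param neo_vafs,other_vafs Non-empty numeric vectors of variant allele
#'   frequencies.
#' @param alternative \code{"greater"} (neoantigens smaller; default) or
#'   \code{"two.sided"}.
#' @return list with \code{D} and \code{p_value}.
#' @export
vafDepletionKS <- function(neo_vafs, other_vafs,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(neo_vafs) || !length(other_vafs))
    stop("empty VAF input", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(neo_vafs, other_vafs,
                                        alternative = alternative))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Paired small-subclone VAF-window test
#'
#' For each biopsy carrying both classes, the proportion of
#' high-immunogenicity neoantigens and of nonimmunogenic mutations whose
#' VAF falls strictly inside the window (default 0.05 < VAF < 0.1, the
#' small-subclone range); compared by a two-sided paired Wilcoxon
#' signed-rank test across biopsies.
#'
#' @param vaf Numeric VAFs.
#' @param immunogenic Logical, parallel: high-immunogenicity neoantigen?
#' @param biopsy Biopsy (sample) id, parallel.
#' @param window Open interval (default \code{c(0.05, 0.1)}); boundary
#'   values are excluded.
#' @param min_pairs Minimum biopsies with both classes (default 3).
#' @return list with \code{per_biopsy} data.frame and \code{p_value}.
#' @export
subcloneWindowTest <- function(vaf, immunogenic, biopsy,
                               window = c(0.05, 0.1), min_pairs = 3) {
  stopifnot(length(vaf) == length(immunogenic),
            length(vaf) == length(biopsy))
  inWin <- vaf > window[1] & vaf < window[2]
  df <- data.frame(vaf = vaf, immunogenic = immunogenic, biopsy = biopsy,
                   inWin = inWin)
  per <- lapply(split(df, df$biopsy), function(d) {
    if (!any(d$immunogenic) || !any(!d$immunogenic)) return(NULL)
    data.frame(biopsy = d$biopsy[1],
               prop_immunogenic = mean(d$inWin[d$immunogenic]),
               prop_nonimmunogenic = mean(d$inWin[!d$immunogenic]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < min_pairs)
    stop("not evaluable: fewer than ", min_pairs,
         " biopsies with both classes", call. = FALSE)
  rownames(per) <- NULL
  list(per_biopsy = per,
       p_value = .pairedWilcoxon(per$prop_immunogenic,
                                 per$prop_nonimmunogenic))
}

#' Mixed-model test with Patient as a random effect
#'
#' Likelihood-ratio comparison of random-intercept models with and without
#' the tested fixed effect: \code{value ~ group + (1 | patient)} against
#' \code{value ~ (1 | patient)}, both by maximum likelihood; the reported
#' p is the chi-squared LRT p. This is the contract used whenever several
#' samples per patient enter a group comparison.
#'
#' @param values Numeric response.
#' @param patient Patient id, parallel.
#' @param group Fixed-effect labels (>= 2 levels), parallel.
#' @return list with \code{p_value}, \code{estimate} (non-intercept fixed
#'   effects), \code{direction} (sign of the first effect).
#' @export
patientRandomEffectTest <- function(values, patient, group) {
  df <- data.frame(y = values, patient = factor(patient),
                   group = factor(group))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$patient)) < 2)
    stop("degenerate design: need >= 2 patients", call. = FALSE)
  if (nlevels(droplevels(df$group)) < 2)
    stop("degenerate design: need >= 2 fixed-effect levels", call. = FALSE)
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ group + (1 | patient), data = df, REML = FALSE)))
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ (1 | patient), data = df, REML = FALSE)))
  an <- suppressMessages(anova(null, full))
  est <- lme4::fixef(full)[-1]
  list(p_value = an[["Pr(>Chisq)"]][2], estimate = est,
       direction = sign(unname(est[1])))
}

#' Multivariable beta regression of proportional burden
#'
#' Logit-link beta regression of a proportion on sample-level covariates
#' (sample type, tissue, escape status, purity) with patient encoded as a
#' categorical fixed effect; patient coefficients are summarised by their
#' min-max range in the report. Proportions exactly at 0 or 1 are pulled
#' inside the open interval with the standard (y (n-1) + 0.5)/n
#' compression before fitting.
#'
#' @param data data.frame containing the response and covariates.
#' @param response Response column name (a proportion in [0, 1]).
#' @param covariates Covariate column names present in \code{data};
#'   \code{patient_id} is treated as the patient factor.
#' @param conf_level CI level (default 0.95).
#' @return list with \code{coefficients} (term, estimate, ci_low, ci_high,
#'   p_value), \code{patient_range} (min/max patient coefficient),
#'   \code{failed} and, on failure, \code{message}.
#' @export
proportionRegression <- function(data, response = "proportional_burden",
                                 covariates = c("region", "tissue",
                                                "purity", "patient_id"),
                                 conf_level = 0.95) {
  covariates <- intersect(covariates, names(data))
  df <- data[, c(response, covariates)]
  df <- df[stats::complete.cases(df), ]
  y <- df[[response]]
  if (any(y < 0 | y > 1)) stop("response must be a proportion in [0, 1]")
  n <- length(y)
  df$.y <- (y * (n - 1) + 0.5) / n      # boundary compression
  for (v in covariates)
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  drop1lvl <- vapply(covariates, function(v)
    is.factor(df[[v]]) && nlevels(droplevels(df[[v]])) < 2, logical(1))
  covariates <- covariates[!drop1lvl]
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    glmmTMB::glmmTMB(fml, data = df, family = glmmTMB::beta_family()),
    error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition"))
    return(list(coefficients = NULL, patient_range = NULL, failed = TRUE,
                message = conditionMessage(fit)))
  sm <- summary(fit)$coefficients$cond
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   ci_low = sm[, "Estimate"] - z * sm[, "Std. Error"],
                   ci_high = sm[, "Estimate"] + z * sm[, "Std. Error"],
                   p_value = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE,
                   row.names = NULL)
  isPat <- grepl("^patient_id", co$term)
  pr <- if (any(isPat)) range(co$estimate[isPat]) else NULL
  list(coefficients = co, patient_range = pr, failed = FALSE)
}
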