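#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Order-preserving q-values: `q_(i) = min_{j >= i} m p_(j) / j` over the
#' ranked p-values. Significance in downstream reports is flagged at
#' `q < 0.05`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_with("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-variant genotype-phenotype association by linear model
#'
#' Fits `phenotype ~ dosage + covariates` per variant (identity-link GLM),
#' reports the dosage Wald test, and adjusts over all tested variants with
#' [bh_fdr()]. Monomorphic variants, variants below the MAF floor, variants
#' tested on fewer than `min_n` samples and singular designs are skipped
#' with a recorded reason.
#'
#' @param dosages samples x variants matrix with entries 0/1/2.
#' @param phenotype numeric response per sample.
#' @param covariates optional data.frame of per-sample covariates.
#' @param maf_min minor-allele-frequency floor.
#' @param min_n minimum complete observations per variant.
#' @return list with `results` (data.frame `variant`, `n`, `beta`, `se`,
#'   `p`, `q`, `maf`, `significant` at q < 0.05) and `skipped`
#'   (`variant`, `reason`).
#' @export
gwas_glm <- function(dosages, phenotype, covariates = NULL, maf_min = 0.01,
                     min_n = 10L) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(phenotype))
  vn <- colnames(dosages)
  if (is.null(vn)) vn <- sprintf("v%d", seq_len(ncol(dosages)))
  res <- list(); skipped <- list()
  for (j in seq_len(ncol(dosages))) {
    d <- dosages[, j]
    ok <- stats::complete.cases(d, phenotype,
                                if (is.null(covariates)) rep(0, length(d))
                                else covariates)
    n <- sum(ok)
    maf <- min(mean(d[ok]) / 2, 1 - mean(d[ok]) / 2)
    if (length(unique(d[ok])) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(variant = vn[j],
                                                    reason = "monomorphic")
      next
    }
    if (maf < maf_min) {
      skipped[[length(skipped) + 1L]] <- data.frame(variant = vn[j],
                                                    reason = "maf_below_floor")
      next
    }
    if (n < min_n) {
      skipped[[length(skipped) + 1L]] <- data.frame(variant = vn[j],
                                                    reason = "too_few_samples")
      next
    }
    dat <- data.frame(y = phenotype[ok], dosage = d[ok])
    if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients
    if (!"dosage" %in% rownames(co) || anyNA(fit$coefficients)) {
      skipped[[length(skipped) + 1L]] <- data.frame(variant = vn[j],
                                                    reason = "singular_design")
      next
    }
    res[[length(res) + 1L]] <- data.frame(
      variant = vn[j], n = n, beta = co["dosage", "Estimate"],
      se = co["dosage", "Std. Error"], p = co["dosage", "Pr(>|t|)"],
      maf = maf, stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(variant = character(), n = integer(), beta = numeric(),
               se = numeric(), p = numeric(), maf = numeric())
  results$q <- bh_fdr(results$p)
  results$significant <- !is.na(results$q) & results$q < 0.05
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(variant = character(), reason = character())
  list(results = results, skipped = skipped)
}

#' Group comparisons of a phenotype
#'
#' `unpaired_t`: two-group Student t-test. `one_sample_t`: t-test of a small
#' carrier group against a reference mean, the design used when only a
#' couple of carriers exist. `anova_dunnett`: one-way ANOVA with Dunnett
#' contrasts of every group against the reference (first level), adjusted
#' via the multivariate-t distribution.
#'
#' @param values numeric phenotype values.
#' @param groups factor of group labels (ignored for `one_sample_t`).
#' @param test one of `unpaired_t`, `one_sample_t`, `anova_dunnett`.
#' @param mu0 reference mean for `one_sample_t`.
#' @param var_equal use pooled variance in `unpaired_t`.
#' @return list with `statistic`, `df`, `p`, and for Dunnett a
#'   `comparisons` data.frame with adjusted p-values.
#' @export
group_compare <- function(values, groups = NULL,
                          test = c("unpaired_t", "one_sample_t",
                                   "anova_dunnett"),
                          mu0 = NULL, var_equal = TRUE) {
  test <- match.arg(test)
  if (test == "one_sample_t") {
    if (is.null(mu0)) stop_with("one_sample_t requires mu0")
    tt <- stats::t.test(values, mu = mu0)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop_with("%s requires >= 2 groups", test)
  if (any(table(groups) < 2L))
    stop_with("each group needs >= 2 values for %s", test)
  if (test == "unpaired_t") {
    if (nlevels(groups) != 2L) stop_with("unpaired_t requires exactly 2 groups")
    sp <- split(values, groups)
    if (stats::sd(values) == 0)
      return(list(statistic = 0, df = length(values) - 2, p = 1))
    tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = var_equal)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  dn <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(dn)
  comparisons <- data.frame(
    comparison = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    p_adjusted = unname(sm$test$pvalues), stringsAsFactors = FALSE)
  list(statistic = an$`F value`[1], df = an$Df,
       p = an$`Pr(>F)`[1], comparisons = comparisons)
}

#' Kaplan-Meier transfusion-free survival with log-rank comparison
#'
#' Product-limit estimates with right censoring (age at first transfusion,
#' censored at last follow-up for never-transfused patients) and a log-rank
#' chi-square over groups with `g - 1` degrees of freedom.
#'
#' @param times non-negative times (years).
#' @param events event flags (1/TRUE = transfused).
#' @param groups group labels (>= 2 groups).
#' @return list with `fit` (a `survfit` object with per-group KM curves),
#'   `chisq`, `df`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop_with("log-rank needs >=2 groups")
  if (sum(events) < 1L) stop_with("log-rank needs at least one event")
  dat <- data.frame(time = times, event = as.integer(events), g = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- nlevels(groups) - 1L
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Beneficial-allele burden score and trend test
#'
#' The burden score counts beneficial allele copies carried by each sample
#' over a catalog of known HbF-raising variants; the accumulated effect on
#' the phenotype is assessed by the linear trend `phenotype ~ score`.
#'
#' @param sample_dosages samples x variants dosage matrix (0/1/2).
#' @param beneficial_catalog character vector of variant names counted as
#'   beneficial (must refer to columns of `sample_dosages`; absent variants
#'   count 0 with a warning).
#' @param phenotype optional numeric response; when supplied the trend test
#'   is run.
#' @return list with `score` per sample and, with a phenotype, `trend`
#'   (`slope`, `se`, `p`).
#' @export
burden_score <- function(sample_dosages, beneficial_catalog,
                         phenotype = NULL) {
  sample_dosages <- as.matrix(sample_dosages)
  have <- intersect(beneficial_catalog, colnames(sample_dosages))
  missing <- setdiff(beneficial_catalog, colnames(sample_dosages))
  if (length(missing))
    warning("catalog variants absent from call set (counted 0): ",
            paste(missing, collapse = ", "))
  score <- if (length(have))
    as.integer(rowSums(sample_dosages[, have, drop = FALSE])) else
    rep(0L, nrow(sample_dosages))
  out <- list(score = score)
  if (!is.null(phenotype)) {
    if (stats::sd(score) == 0) {
      out$trend <- list(slope = NA_real_, se = NA_real_, p = NA_real_)
    } else {
      fit <- summary(stats::lm(phenotype ~ score))$coefficients
      out$trend <- list(slope = fit["score", "Estimate"],
                        se = fit["score", "Std. Error"],
                        p = fit["score", "Pr(>|t|)"])
    }
  }
  out
}
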