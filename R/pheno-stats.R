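# Strain-level statistics for wide phenotype tables.
#
# Per-strain modified z-scores (robust outlier classification), broad-sense
# heritability h2 = VA / (VA + VE), pairwise-complete Pearson correlations,
# and one-/two-way ANOVA with a strain x age interaction. Tables are rows
# of (animal_id, strain, age_days, trait columns); trait cells may be NA.

#' Classify a modified z-score
#'
#' Thresholds are exclusive at +/-1 and +/-3: a score must be strictly
#' larger than 1 (3) to be high (very high), and strictly lower than -1
#' (-3) to be low (very low).
#'
#' @param z numeric vector of modified z-scores.
#' @return character vector in
#'   {"very_low", "low", "normal", "high", "very_high"}.
#' @export
classify_z <- function(z) {
  ifelse(is.na(z), NA_character_,
    ifelse(z > 3, "very_high",
      ifelse(z > 1, "high",
        ifelse(z < -3, "very_low",
          ifelse(z < -1, "low", "normal")))))
}

#' Per-strain summaries with modified z-scores for one trait
#'
#' The modified z-score of a strain is
#' `0.6745 * (strain median - population median) / strain MAD`, where MAD
#' is the raw median absolute deviation from the strain median (no
#' consistency factor: the 0.6745 multiplier plays that role). When the
#' MAD is zero the fallback is
#' `0.98 * (strain median - population median) / strain mean absolute
#' deviation`. The population median pools all non-missing animals of all
#' strains. Scores above 1 / 3 (below -1 / -3) mark high / very high
#' (low / very low) outlier strains.
#'
#' @param table phenotype table (see [gen_phenotypes()] / [read_phenotypes()]).
#' @param trait name of the trait column.
#' @return tibble, one row per strain: `strain`, `n`, `mean`, `median`,
#'   `sd`, `mad`, `mean_ad`, `z`, `z_class`. Strains whose MAD and mean AD
#'   are both zero while their median differs from the population median
#'   get an infinite z (with a warning) and the matching extreme class.
#' @export
strain_summaries <- function(table, trait) {
  y <- table[[trait]]
  if (is.null(y)) stop(sprintf("no trait column '%s'", trait), call. = FALSE)
  keep <- !is.na(y)
  if (!any(keep)) stop(sprintf("trait '%s' is entirely missing", trait),
                       call. = FALSE)
  y <- y[keep]; strain <- table$strain[keep]
  strains <- unique(strain)
  if (length(strains) < 2L) {
    stop("need >= 2 strains with data", call. = FALSE)
  }
  pop_med <- stats::median(y)
  rows <- lapply(strains, function(s) {
    v <- y[strain == s]
    med <- stats::median(v)
    mad_raw <- stats::median(abs(v - med))
    mean_ad <- mean(abs(v - med))
    num <- med - pop_med
    if (mad_raw > 0) {
      z <- 0.6745 * num / mad_raw
    } else if (mean_ad > 0) {
      z <- 0.98 * num / mean_ad
    } else if (num == 0) {
      z <- 0
    } else {
      warning(sprintf(
        "strain '%s': zero spread but off-population median; z is infinite", s),
        call. = FALSE)
      z <- sign(num) * Inf
    }
    tibble::tibble(strain = s, n = length(v), mean = mean(v), median = med,
                   sd = stats::sd(v), mad = mad_raw, mean_ad = mean_ad,
                   z = z, z_class = classify_z(z))
  })
  do.call(rbind, rows)
}

#' Broad-sense heritability of one trait
#'
#' `h2 = VA / (VA + VE)`: the between-strain variance over the total
#' phenotypic variance. Two estimators of the components are provided.
#' `strain_mean_variance` (default): VA = sample variance of the strain
#' means, VE = unweighted mean of the within-strain sample variances.
#' `anova_mom`: method-of-moments from the one-way ANOVA mean squares,
#' VA = (MSB - MSW) / n0 (clipped at 0) with n0 the effective per-strain
#' n for unbalanced data, VE = MSW.
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param estimator "strain_mean_variance" or "anova_mom".
#' @return one-row tibble: `trait`, `va`, `ve`, `h2`, `estimator`,
#'   `n_strains`, `n_animals`.
#' @export
heritability <- function(table, trait,
                         estimator = c("strain_mean_variance", "anova_mom")) {
  estimator <- match.arg(estimator)
  y <- table[[trait]]
  keep <- !is.na(y)
  y <- y[keep]; strain <- factor(table$strain[keep])
  strain <- droplevels(strain)
  k <- nlevels(strain)
  if (k < 2L) stop("heritability needs >= 2 strains with data", call. = FALSE)
  n_i <- as.vector(table(strain))
  if (max(n_i) < 2L) stop("need >= 2 animals in at least one strain",
                          call. = FALSE)
  if (estimator == "strain_mean_variance") {
    means <- tapply(y, strain, mean)
    va <- stats::var(as.vector(means))
    wvars <- tapply(y, strain, function(v) if (length(v) > 1) stats::var(v) else NA_real_)
    ve <- mean(wvars, na.rm = TRUE)
  } else {
    fit <- stats::aov(y ~ strain)
    tab <- summary(fit)[[1]]
    msb <- tab["strain", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    N <- length(y)
    n0 <- (N - sum(n_i^2) / N) / (k - 1)
    va <- max(0, (msb - msw) / n0)
    ve <- msw
  }
  if (!is.finite(va) || !is.finite(ve) || va + ve <= 0) {
    stop(sprintf("trait '%s' is degenerate: VA + VE is zero", trait),
         call. = FALSE)
  }
  tibble::tibble(trait = trait, va = va, ve = ve, h2 = va / (va + ve),
                 estimator = estimator, n_strains = k, n_animals = length(y))
}

#' Pairwise-complete Pearson correlations between traits
#'
#' Each cell uses the rows where both traits are non-missing; cells with
#' fewer than `min_pairs` complete pairs are reported NA.
#'
#' @param table phenotype table.
#' @param traits character vector of trait column names.
#' @param min_pairs minimum complete pairs per reported cell.
#' @return list with `r` (trait x trait correlation matrix, unit diagonal)
#'   and `n` (complete-pair counts), plus a long-format tibble `long`
#'   (`trait_a`, `trait_b`, `r`, `n`; upper triangle).
#' @export
pairwise_pearson <- function(table, traits, min_pairs = 3L) {
  x <- as.matrix(table[, traits, drop = FALSE])
  p <- length(traits)
  r <- diag(1, p); nmat <- matrix(0L, p, p)
  dimnames(r) <- dimnames(nmat) <- list(traits, traits)
  diag(nmat) <- colSums(!is.na(x))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      r[i, j] <- r[j, i] <- if (sum(ok) >= min_pairs) {
        stats::cor(x[ok, i], x[ok, j])
      } else NA_real_
    }
  }
  long <- do.call(rbind, lapply(seq_len(p - 1L), function(i) {
    tibble::tibble(trait_a = traits[i], trait_b = traits[(i + 1L):p],
                   r = r[i, (i + 1L):p], n = nmat[i, (i + 1L):p])
  }))
  list(r = r, n = nmat, long = long)
}

.anova_tidy <- function(fit, trait) {
  tab <- stats::anova(fit)
  tibble::tibble(trait = trait,
                 term = rownames(tab),
                 df = tab$Df,
                 sumsq = tab$`Sum Sq`,
                 meansq = tab$`Mean Sq`,
                 statistic = tab$`F value`,
                 p = tab$`Pr(>F)`)
}

#' One-way ANOVA of a trait on a grouping column
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param factor_col grouping column (e.g. "strain"); coerced to factor.
#' @return tidy ANOVA tibble (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p`), one row per term plus residuals.
#' @export
one_way_anova <- function(table, trait, factor_col = "strain") {
  keep <- !is.na(table[[trait]]) & !is.na(table[[factor_col]])
  d <- data.frame(y = table[[trait]][keep],
                  g = factor(table[[factor_col]][keep]))
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2L) {
    stop("one-way ANOVA needs >= 2 factor levels with data", call. = FALSE)
  }
  out <- .anova_tidy(stats::lm(y ~ g, data = d), trait)
  out$term[out$term == "g"] <- factor_col
  out
}

#' Two-way ANOVA: strain, age, and their interaction
#'
#' Fits `trait ~ strain + age + strain:age` with age continuous in days
#' and strain a factor, using sequential (type-I) sums of squares in that
#' term order.
#'
#' @param table phenotype table with `strain` and `age_days` columns.
#' @param trait trait column name.
#' @return tidy ANOVA tibble with rows for `strain`, `age_days`,
#'   `strain:age_days` and `Residuals`.
#' @export
two_way_anova <- function(table, trait) {
  keep <- !is.na(table[[trait]]) & !is.na(table$age_days)
  d <- data.frame(y = table[[trait]][keep],
                  strain = factor(table$strain[keep]),
                  age_days = table$age_days[keep])
  d$strain <- droplevels(d$strain)
  if (nlevels(d$strain) < 2L) stop("need >= 2 strains", call. = FALSE)
  if (stats::var(d$age_days) == 0) stop("age does not vary", call. = FALSE)
  if (stats::var(d$y) == 0) stop("zero-variance trait", call. = FALSE)
  .anova_tidy(stats::lm(y ~ strain + age_days + strain:age_days, data = d),
              trait)
}
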