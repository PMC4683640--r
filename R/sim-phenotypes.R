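# Synthetic strain-panel phenotype tables with known variance components.
#
# Model: y_ij = grand_mean + s_i + age_slope * age_ij + e_ij, with strain
# effects s_i ~ N(0, va) and residuals e_ij ~ N(0, ve). Ages are uniform
# over the observed survey range (70-461 days by default). Cells can be
# masked missing at a configurable rate, as in real wide trait tables.

#' Configuration for the phenotype-table generator
#'
#' @param n_strains number of inbred strains (>= 2).
#' @param n_per_strain animals per strain.
#' @param grand_mean trait grand mean.
#' @param va between-strain (genetic) variance of the simulated trait.
#' @param ve within-strain (environmental) variance.
#' @param age_slope linear age effect per day.
#' @param age_range_days length-2 interval for uniform ages.
#' @param missing_rate probability a trait cell is masked missing.
#' @param trait name of the simulated trait column.
#' @param seed integer seed.
#' @return config list of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(n_strains = 8L,
                             n_per_strain = 25L,
                             grand_mean = 0,
                             va = 0.7,
                             ve = 0.3,
                             age_slope = 0,
                             age_range_days = c(70, 461),
                             missing_rate = 0,
                             trait = "trait",
                             seed = 1L) {
  if (n_strains < 2L) stop("`n_strains` must be >= 2 (heritability is undefined for one strain)",
                           call. = FALSE)
  check_pos(n_per_strain, "n_per_strain")
  check_pos(va, "va", strict = FALSE)
  check_pos(ve, "ve", strict = FALSE)
  if (va + ve <= 0) stop("`va + ve` must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(length(age_range_days) == 2L, age_range_days[1] > 0,
            age_range_days[2] >= age_range_days[1])
  structure(list(n_strains = as.integer(n_strains),
                 n_per_strain = as.integer(n_per_strain),
                 grand_mean = grand_mean, va = va, ve = ve,
                 age_slope = age_slope, age_range_days = age_range_days,
                 missing_rate = missing_rate, trait = trait,
                 seed = as.integer(seed)),
            class = "pheno_sim_config")
}

#' Generate a synthetic phenotype table
#'
#' @param cfg a [pheno_sim_config()].
#' @return tibble with columns `animal_id`, `strain`, `age_days`, and one
#'   trait column (NA where masked missing).
#' @export
gen_phenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "pheno_sim_config"))
  with_seed(cfg$seed, {
    k <- cfg$n_strains; n <- cfg$n_per_strain
    strain_eff <- stats::rnorm(k, 0, sqrt(cfg$va))
    strain <- rep(sprintf("S%02d", seq_len(k)), each = n)
    age <- stats::runif(k * n, cfg$age_range_days[1], cfg$age_range_days[2])
    y <- cfg$grand_mean + rep(strain_eff, each = n) +
      cfg$age_slope * age + stats::rnorm(k * n, 0, sqrt(cfg$ve))
    if (cfg$missing_rate > 0) {
      y[stats::runif(k * n) < cfg$missing_rate] <- NA_real_
    }
    out <- tibble::tibble(
      animal_id = sprintf("A%04d", seq_len(k * n)),
      strain = strain,
      age_days = age
    )
    out[[cfg$trait]] <- y
    out
  })
}
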