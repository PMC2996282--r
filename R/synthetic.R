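# Seeded synthetic cohort generator. The generative model is a latent
# four-component construction: basal secretion B (sets fasting insulin),
# early-phase amplitude E (glucose-stimulated response, dominates the
# 0-30 min insulin rise), incretin potentiation K (sustains secretion over
# the 30-120 min plateau, expressed more strongly in C-peptide), and
# insulin sensitivity S (declines with BMI and age). SNP minor alleles act
# multiplicatively on the component their route targets, so early-window
# indices are preferentially sensitive to early_phase SNPs and full-window
# C-peptide indices to incretin_phase SNPs. Noise is multiplicative
# lognormal, which makes the log-scale regression model of the analysis
# correctly specified (an additive-noise switch is provided for
# misspecification stress tests).

#' Define a simulated SNP
#'
#' @param snp_id Identifier used as the genotype column name.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param route Latent component the minor allele acts on:
#'   \code{"early_phase"} (glucose-stimulated early secretion),
#'   \code{"incretin_phase"} (late, incretin-potentiated secretion),
#'   \code{"basal"} (fasting secretion) or \code{"null"}.
#' @param per_allele_effect Multiplicative factor applied to the targeted
#'   component per minor allele (e.g. 0.9 = 10% reduction per allele).
#' @return List of class \code{snp_spec}.
#' @export
snp_spec <- function(snp_id, maf, route = c("early_phase", "incretin_phase",
                                            "basal", "null"),
                     per_allele_effect = 1) {
  route <- match.arg(route)
  stopifnot(is.character(snp_id), length(snp_id) == 1,
            maf > 0, maf <= 0.5, per_allele_effect > 0)
  structure(list(snp_id = snp_id, maf = maf, route = route,
                 per_allele_effect = per_allele_effect),
            class = "snp_spec")
}

#' Default six-SNP panel
#'
#' Three SNPs routed through glucose-stimulated early-phase secretion and
#' three through the incretin axis, with allele frequencies typical of
#' confirmed type-2-diabetes risk variants. A per-allele factor of 1
#' switches a route off (null SNPs at the stated frequencies).
#'
#' @param effect_early Per-allele factor for the three early-phase SNPs.
#' @param effect_incretin Per-allele factor for the three incretin SNPs.
#' @return List of six \code{\link{snp_spec}} objects.
#' @export
default_snp_panel <- function(effect_early = 0.9, effect_incretin = 0.9) {
  route_e <- if (effect_early == 1) "null" else "early_phase"
  route_i <- if (effect_incretin == 1) "null" else "incretin_phase"
  list(snp_spec("gsis_1", 0.30, route_e, effect_early),
       snp_spec("gsis_2", 0.40, route_e, effect_early),
       snp_spec("gsis_3", 0.32, route_e, effect_early),
       snp_spec("isis_1", 0.30, route_i, effect_incretin),
       snp_spec("isis_2", 0.40, route_i, effect_incretin),
       snp_spec("isis_3", 0.15, route_i, effect_incretin))
}

#' Simulation configuration
#'
#' Defaults emulate the marginal structure of a middle-European
#' type-2-diabetes risk cohort: N = 1350, one third men, age 38 +/- 12 y,
#' BMI median 27 kg/m2, fasting glucose 4.9 mmol/l, fasting insulin median
#' 47 pmol/l (mean ~52), 30-min insulin ~470 pmol/l, fasting C-peptide
#' ~11x fasting insulin, and a 20% IVGTT subset.
#'
#' @param n_subjects Cohort size.
#' @param snps List of \code{\link{snp_spec}} objects.
#' @param frac_male Proportion of men.
#' @param age_mean,age_sd Age distribution (years), truncated to 20-75.
#' @param bmi_meanlog,bmi_sdlog Lognormal BMI parameters (kg/m2).
#' @param g0_meanlog,g0_sdlog Lognormal fasting glucose (mmol/l).
#' @param ins0_median Median fasting insulin (pmol/l).
#' @param sd_latent Biological lognormal sd of the latent components.
#' @param cv_glc,cv_ins,cv_cp Assay coefficients of variation
#'   (lognormal sd on the log scale) per analyte sample.
#' @param frac_ivgtt Fraction of subjects with an IVGTT.
#' @param plant_negative Number of subjects whose 30-min insulin is forced
#'   below fasting insulin (negative insulinogenic index), for testing the
#'   exclusion rule; planted ids are recorded in the ground truth.
#' @param noise_model \code{"multiplicative"} (lognormal, default) or
#'   \code{"additive"} (Gaussian, misspecification stress test).
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 1350, snps = default_snp_panel(),
                       frac_male = 1 / 3, age_mean = 38, age_sd = 12,
                       bmi_meanlog = log(27), bmi_sdlog = 0.22,
                       g0_meanlog = log(4.89), g0_sdlog = 0.078,
                       ins0_median = 47, sd_latent = 0.35,
                       cv_glc = 0.015, cv_ins = 0.08, cv_cp = 0.06,
                       frac_ivgtt = 0.2, plant_negative = 0,
                       noise_model = c("multiplicative", "additive"),
                       seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_subjects > 0, frac_male >= 0, frac_male <= 1,
            age_sd >= 0, bmi_sdlog >= 0, g0_sdlog >= 0, sd_latent >= 0,
            cv_glc >= 0, cv_ins >= 0, cv_cp >= 0,
            frac_ivgtt >= 0, frac_ivgtt <= 1,
            plant_negative >= 0, plant_negative <= n_subjects)
  for (s in snps) {
    if (!inherits(s, "snp_spec")) stop("snps must be snp_spec objects", call. = FALSE)
  }
  ids <- vapply(snps, `[[`, "", "snp_id")
  if (anyDuplicated(ids)) stop("duplicate SNP ids", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate HWE genotypes
#'
#' Each genotype is an independent Binomial(2, maf) minor-allele count
#' (Hardy-Weinberg proportions, no linkage disequilibrium).
#'
#' @param n Number of subjects.
#' @param snps List of \code{\link{snp_spec}} objects.
#' @return Integer matrix, one column per SNP.
#' @export
simulate_genotypes <- function(n, snps) {
  g <- vapply(snps, function(s) stats::rbinom(n, 2L, s$maf), integer(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  colnames(g) <- vapply(snps, `[[`, "", "snp_id")
  g
}

# Time-course kernels over minutes {0,30,60,90,120}. g peaks early and
# decays fast (first-phase insulin); h rises to a late plateau (incretin-
# potentiated second phase); the C-peptide versions decay more slowly,
# honouring C-peptide's longer circulating half-life.
KERNEL_GLC <- c(0, 1, 0.85, 0.5, 0.2)
KERNEL_INS_E <- c(0, 1, 0.5, 0.2, 0.05)
KERNEL_INS_K <- c(0, 0.15, 0.7, 1, 0.95)
KERNEL_CP_E <- c(0, 0.9, 0.7, 0.45, 0.25)
KERNEL_CP_K <- c(0, 0.1, 0.6, 1, 1)
KERNEL_IVGTT <- c(0, 1.3, 1.15, 0.95, 0.8, 0.65)
CP_BASAL_RATIO <- 11   # fasting C-peptide / fasting insulin
CP_E_SCALE <- 2.2      # early-phase weight in C-peptide
CP_K_SCALE <- 7.0      # incretin weight in C-peptide (late dominance)
E_SCALE <- 400         # pmol/l early-phase insulin amplitude
K_SCALE <- 350         # pmol/l incretin-phase amplitude
GLC_RISE <- 3.2        # mmol/l median 30-min glucose excursion

route_factor <- function(genotypes, snps, route) {
  fac <- rep(1, nrow(genotypes))
  for (s in snps) {
    if (s$route == route && s$per_allele_effect != 1) {
      fac <- fac * s$per_allele_effect^genotypes[, s$snp_id]
    }
  }
  fac
}

# Assay noise: multiplicative lognormal by default; the additive variant
# perturbs by cv x the analyte's cohort-mean level (misspecification test).
apply_noise <- function(true, cv, model) {
  if (cv == 0) return(true)
  z <- matrix(stats::rnorm(length(true), 0, cv), nrow(true), ncol(true))
  if (model == "multiplicative") {
    true * exp(z)
  } else {
    true + z * mean(true)
  }
}

#' Simulate subject records for given genotypes
#'
#' Vectorised core of the generator: draws covariates and latent
#' components, applies the allelic route factors, and builds the OGTT
#' glucose/insulin/C-peptide curves (and IVGTT insulin for a requested
#' subset). See the package vignette for the generative model.
#'
#' @param genotypes Integer matrix from \code{\link{simulate_genotypes}}.
#' @param config A \code{\link{sim_config}}.
#' @param ivgtt Logical vector marking subjects with an IVGTT.
#' @return List: \code{cohort} data frame in the standard schema and
#'   \code{latent} data frame of the per-subject true components.
#' @export
simulate_subjects <- function(genotypes, config, ivgtt = NULL) {
  n <- nrow(genotypes)
  if (is.null(ivgtt)) ivgtt <- rep(FALSE, n)
  sex <- ifelse(stats::runif(n) < config$frac_male, "male", "female")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 20), 75)
  bmi <- stats::rlnorm(n, config$bmi_meanlog, config$bmi_sdlog)

  sdl <- config$sd_latent
  S <- exp(-1.1 * (log(bmi) - config$bmi_meanlog) -
             0.004 * (age - config$age_mean) + stats::rnorm(n, 0, sdl))
  B <- config$ins0_median * S^(-0.65) * exp(stats::rnorm(n, 0, 0.30)) *
    route_factor(genotypes, config$snps, "basal")
  E <- E_SCALE * exp(stats::rnorm(n, 0, sdl)) *
    route_factor(genotypes, config$snps, "early_phase")
  K <- K_SCALE * exp(stats::rnorm(n, 0, sdl)) *
    route_factor(genotypes, config$snps, "incretin_phase")

  g0 <- stats::rlnorm(n, config$g0_meanlog, config$g0_sdlog)
  rise <- GLC_RISE * (S * E / E_SCALE)^(-0.25) * exp(stats::rnorm(n, 0, 0.15))

  glc_true <- outer(g0, rep(1, 5)) + outer(rise, KERNEL_GLC)
  ins_true <- outer(B, rep(1, 5)) + outer(E, KERNEL_INS_E) +
    outer(K, KERNEL_INS_K)
  cp_true <- CP_BASAL_RATIO * outer(B, rep(1, 5)) +
    CP_E_SCALE * outer(E, KERNEL_CP_E) + CP_K_SCALE * outer(K, KERNEL_CP_K)

  nm <- config$noise_model
  glc <- apply_noise(glc_true, config$cv_glc, nm)
  ins <- apply_noise(ins_true, config$cv_ins, nm)
  cp <- apply_noise(cp_true, config$cv_cp, nm)

  iv <- matrix(NA_real_, n, 6)
  if (any(ivgtt)) {
    m <- sum(ivgtt)
    iv_true <- outer(B[ivgtt], rep(1, 6)) + outer(E[ivgtt], KERNEL_IVGTT)
    iv[ivgtt, ] <- apply_noise(iv_true, config$cv_ins, nm)
  }

  cohort <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                       sex = sex, age = age, bmi = bmi,
                       stringsAsFactors = FALSE)
  cohort[ogtt_cols("glc")] <- as.data.frame(glc)
  cohort[ogtt_cols("ins")] <- as.data.frame(ins)
  cohort[ogtt_cols("cpep")] <- as.data.frame(cp)
  cohort[paste0("ivgtt_ins_", AIR_MINUTES)] <- as.data.frame(iv)
  cohort <- cbind(cohort, as.data.frame(genotypes))

  latent <- data.frame(subject_id = cohort$subject_id, B = B, E = E, K = K,
                       S = S, stringsAsFactors = FALSE)
  list(cohort = cohort, latent = latent)
}

#' Simulate a full cohort with ground truth
#'
#' Draws genotypes, subject records and the IVGTT subset under the
#' configured seed; optionally plants subjects with a negative
#' insulinogenic index (30-min insulin forced below fasting insulin) to
#' exercise the exclusion rule. A fixed (config, seed) pair determines the
#' output bit-for-bit.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{cohort} (standard-schema data frame) and
#'   \code{truth} (list: \code{snps}, \code{latent}, \code{ivgtt_ids},
#'   \code{planted_negative_ids}, \code{seed}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  genotypes <- simulate_genotypes(n, config$snps)
  ivgtt <- stats::runif(n) < config$frac_ivgtt
  sim <- simulate_subjects(genotypes, config, ivgtt)
  cohort <- sim$cohort

  planted <- character(0)
  if (config$plant_negative > 0) {
    pick <- sample.int(n, config$plant_negative)
    cohort$ins_30[pick] <- cohort$ins_0[pick] *
      stats::runif(config$plant_negative, 0.6, 0.9)
    planted <- cohort$subject_id[pick]
  }
  list(cohort = cohort,
       truth = list(snps = config$snps, latent = sim$latent,
                    ivgtt_ids = cohort$subject_id[ivgtt],
                    planted_negative_ids = planted, seed = config$seed))
}
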