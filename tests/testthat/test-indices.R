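test_that("trapezoid AUC matches the printed two-step weighting", {
  expect_equal(trapezoid_auc(rep(1, 5)), 2.0)
  expect_equal(trapezoid_auc(rep(0, 5)), 0.0)
  expect_equal(trapezoid_auc(c(4, 8, 6, 5, 4)), 11.5)
})

test_that("trapezoid AUC is linear and errors on missing samples", {
  set.seed(11)
  for (i in 1:10) {
    x <- runif(5, 0, 10); y <- runif(5, 0, 10)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(trapezoid_auc(a * x + b * y),
                 a * trapezoid_auc(x) + b * trapezoid_auc(y))
  }
  expect_error(trapezoid_auc(c(1, NA, 1, 1, 1), analyte = "insulin",
                             subject = "S1"), "insulin.*S1")
})

test_that("HOMA-B converts insulin units and flags the singular denominator", {
  expect_equal(homa_b(5.5, 60), 100.0)
  expect_equal(homa_b(5.5, 0), 0.0)
  expect_true(is.na(homa_b(3.5, 60)))
  expect_true(is.na(homa_b(3.2, 60)))
  # configurable conversion constant
  expect_equal(homa_b(5.5, 60, pmol_per_uiu = 7.175), 20 * (60 / 7.175) / 2)
})

test_that("insulinogenic indices and oral DI follow the printed formulas", {
  expect_equal(igi1(50, 450, 5, 8), 400 / 3)
  expect_equal(igi2(50, 450, 8), 50.0)
  expect_equal(di_oral(50, 450, 5, 8), (400 / 3) / 50)
  expect_equal(igi1(100, 100, 5, 8), 0)
  expect_equal(igi2(100, 100, 8), 0)
  expect_true(is.na(igi1(50, 450, 6, 6)))
  expect_true(is.na(di_oral(0, 450, 5, 8)))
  expect_lt(igi1(450, 50, 5, 8), 0)  # falling insulin -> negative, not clamped
})

test_that("CIR matches its quadratic-glucose normalisation", {
  expect_equal(cir(450, 8), 100 * 450 / (8 * (8 - 3.89)))
  expect_equal(cir(0, 8), 0)
  expect_true(is.na(cir(450, 3.89)))
  expect_lt(cir(450, 3.5), 0)
})

test_that("first-phase estimate is the printed linear surrogate", {
  expect_equal(first_phase_stumvoll(0, 0, 0), 1283)
  expect_equal(first_phase_stumvoll(50, 450, 8),
               1283 + 1.829 * 450 - 138.7 * 8 + 3.772 * 50)
  expect_gt(first_phase_stumvoll(50, 1e4, 8), first_phase_stumvoll(50, 450, 8))
})

test_that("AUC ratios: two-point sum form for 0-30, trapezoid for 0-120", {
  i <- c(50, 450, 350, 200, 120); g <- c(5, 8, 7, 6, 5.5)
  expect_identical(auc_ratio(i, g, "0-30"), (50 + 450) / (5 + 8))
  # two-point trapezoid weights cancel: same value bit-for-bit
  expect_identical((0.25 * (50 + 450)) / (0.25 * (5 + 8)),
                   auc_ratio(i, g, "0-30"))
  expect_equal(auc_ratio(i, g, "0-120"), trapezoid_auc(i) / trapezoid_auc(g))
  cp <- c(600, 2000, 1800, 1500, 1200)
  expect_equal(auc_ratio(cp, g, "0-30"), 2600 / 13)
  # constants cancel the scaling in either window
  expect_equal(auc_ratio(rep(60, 5), rep(5, 5), "0-30"), 12)
  expect_equal(auc_ratio(rep(60, 5), rep(5, 5), "0-120"), 12)
})

test_that("Matsuda index uses unweighted five-point means", {
  expect_equal(matsuda_isi(rep(5, 5), rep(60, 5)), 10000 / 300)
  g <- c(5, 8, 7, 6, 5.5); i <- c(50, 450, 350, 200, 120)
  expect_equal(matsuda_isi(g, i), 10000 / sqrt(5 * 50 * 6.3 * 234))
  # homogeneity of degree -1 in insulin
  expect_equal(matsuda_isi(g, 2 * i), matsuda_isi(g, i) / 2)
  expect_true(is.na(matsuda_isi(c(5, 0, 7, 6, 5.5), i)))
})

test_that("insulin clearances are the printed ratios", {
  cp <- c(600, 2000, 1800, 1500, 1200); i <- c(50, 450, 350, 200, 120)
  expect_equal(insulin_clearance(cp, i, "fasting"), 12.0)
  expect_equal(insulin_clearance(i, i, "ogtt"), 1.0)
  expect_true(is.na(insulin_clearance(cp, c(0, 450, 350, 200, 120), "fasting")))
})

test_that("AIR uses the printed half-weighted end points (weights sum 2.5)", {
  expect_equal(air_ivgtt(rep(0, 6)), 0)
  expect_equal(air_ivgtt(c(50, 900, 800, 700, 600, 500)), 1637.5)
  expect_equal(air_ivgtt(rep(7, 6)), 2.5 * 7)
  expect_error(air_ivgtt(c(50, NA, 800, 700, 600, 500), subject = "S9"), "S9")
})

test_that("panel is unit-covariant in insulin and c-peptide ratios are not", {
  row <- make_cohort_row("A", glc = c(5, 8, 7, 6, 5.5),
                         ins = c(50, 450, 350, 200, 120),
                         cpep = c(600, 2000, 1800, 1500, 1200))
  row2 <- row
  row2[paste0("ins_", c(0, 30, 60, 90, 120))] <-
    3 * as.numeric(row[paste0("ins_", c(0, 30, 60, 90, 120))])
  p1 <- compute_panel(row); p2 <- compute_panel(row2)
  for (ix in c("insulin_30", "igi1", "igi2", "cir", "auc_ins_0_30",
               "auc_ins_0_120")) {
    expect_equal(p2[[ix]], 3 * p1[[ix]], info = ix)
  }
  for (ix in c("c_peptide_30", "auc_cp_0_30", "auc_cp_0_120")) {
    expect_equal(p2[[ix]], p1[[ix]], info = ix)
  }
})

test_that("negative or undefined secretion indices drive the exclusion rule", {
  ok <- make_cohort_row("keep", glc = c(5, 8, 7, 6, 5.5),
                        ins = c(50, 450, 350, 200, 120),
                        cpep = c(600, 2000, 1800, 1500, 1200))
  neg <- make_cohort_row("drop_neg", glc = c(5.5, 5.0, 6, 5.5, 5.2),
                         ins = c(50, 450, 350, 200, 120),
                         cpep = c(600, 2000, 1800, 1500, 1200))  # G30 < G0
  cohort <- rbind(ok, neg)
  p <- compute_panel(cohort)
  expect_false(p$any_negative[1])
  expect_true(p$any_negative[2])
  ex <- apply_negative_exclusion(cohort, p)
  expect_identical(ex$cohort$subject_id, "keep")
  expect_identical(ex$excluded$subject_id, "drop_neg")
  expect_identical(ex$excluded$reason, "negative_secretion_index")
  # all-positive rising profile is always retained
  expect_true(all(is.na(p$excluded_reason[1])))
})

test_that("planted negative-IGI subjects are excluded exactly", {
  # noiseless cohort: no spontaneous negatives, so the planted count is exact
  cfg0 <- sim_config(n_subjects = 300, plant_negative = 7, seed = 31,
                     sd_latent = 0, cv_glc = 0, cv_ins = 0, cv_cp = 0)
  sim0 <- simulate_cohort(cfg0)
  ex0 <- apply_negative_exclusion(sim0$cohort)
  expect_setequal(ex0$excluded$subject_id, sim0$truth$planted_negative_ids)
  expect_equal(nrow(ex0$excluded), 7)
  # under default noise every planted subject is still caught
  cfg <- sim_config(n_subjects = 300, plant_negative = 7, seed = 31)
  sim <- simulate_cohort(cfg)
  ex <- apply_negative_exclusion(sim$cohort)
  expect_true(all(sim$truth$planted_negative_ids %in% ex$excluded$subject_id))
})

test_that("glucose tolerance classification follows ADA cutoffs", {
  expect_equal(as.character(classify_glucose_tolerance(4.9, 5.6)), "NGT")
  expect_equal(as.character(classify_glucose_tolerance(5.9, 6.2)), "IFG")
  expect_equal(as.character(classify_glucose_tolerance(5.1, 8.7)), "IGT")
  expect_equal(as.character(classify_glucose_tolerance(5.8, 8.0)), "IFG+IGT")
  expect_equal(as.character(classify_glucose_tolerance(7.2, 6.0)), "diabetes")
  expect_equal(as.character(classify_glucose_tolerance(5.0, 11.5)), "diabetes")
})
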