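test_that("adjusted fit matches the normal-equation oracle on a small design", {
  set.seed(101)
  d <- make_direct_frame(20, beta = 0.3)
  res <- fit_adjusted_model(d, index = "y", snp = "g")
  X <- cbind(1, d$g, as.numeric(d$sex == "male"), log(d$age), log(d$bmi),
             log(d$matsuda_isi))
  o <- ols_oracle(X, log(d$y), j = 2)
  expect_equal(res$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(res$se, o$se[2], tolerance = 1e-8)
  expect_equal(res$f_stat, o$f, tolerance = 1e-8)
  expect_equal(res$p_value, o$p, tolerance = 1e-8)
  expect_equal(res$ms_error, o$mse, tolerance = 1e-8)
  expect_equal(res$df2, o$df2)
  expect_equal(res$n_used, 20)
  expect_equal(res$n_coefficients, 6)
})

test_that("planted per-allele effect is recovered within 3 SE", {
  set.seed(202)
  beta <- 0.15
  d <- make_direct_frame(2000, beta = beta)
  res <- fit_adjusted_model(d, index = "y", snp = "g")
  expect_lt(abs(res$beta - beta), 3 * res$se)
  expect_lt(res$p_value, 0.05)
})

test_that("degenerate designs raise informative errors", {
  set.seed(5)
  d <- make_direct_frame(50)
  d$g <- 1L
  expect_error(fit_adjusted_model(d, index = "y", snp = "g"), "collinear")
  expect_error(fit_adjusted_model(d, index = "y", snp = "y"), "must differ")
  d2 <- make_direct_frame(4)
  expect_error(fit_adjusted_model(d2, index = "y", snp = "g"), "usable rows")
})

test_that("rescaling an index leaves the genotype term untouched", {
  set.seed(303)
  d <- make_direct_frame(400, beta = 0.1)
  a <- fit_adjusted_model(d, index = "y", snp = "g")
  d$y <- d$y * 137.5
  b <- fit_adjusted_model(d, index = "y", snp = "g")
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$f_stat, b$f_stat, tolerance = 1e-12)
})

test_that("rows with missing or non-positive values are deleted listwise", {
  set.seed(44)
  d <- make_direct_frame(100, beta = 0.2)
  d$g[1:5] <- NA
  d$y[6] <- -2          # violates positivity before log
  d$bmi[7] <- NA
  res <- fit_adjusted_model(d, index = "y", snp = "g")
  expect_equal(res$n_used, 93)
  expect_equal(res$n_missing, 7)
  expect_equal(res$n_used + res$n_missing, 100)
})

test_that("quartile stratification cuts at sample quartiles, lower-inclusive", {
  f <- cut_quartiles(1:8)
  expect_equal(as.integer(f), rep(1:4, each = 2))
  expect_warning(f2 <- cut_quartiles(rep(3, 20)), "merging")
  expect_equal(nlevels(droplevels(f2)), 1)
})

test_that("quartile-nominal adjustment agrees with continuous adjustment", {
  set.seed(606)
  d <- make_direct_frame(1000, beta = 0.2)
  cont <- fit_adjusted_model(d, index = "y", snp = "g")
  nom <- quartile_nominal_fit(d, index = "y", snp = "g")
  expect_equal(sign(cont$beta), sign(nom$beta))
  expect_lt(abs(log10(cont$p_value) - log10(nom$p_value)), 1)
  # intercept + genotype + sex + 3 quartile factors x 3 dummies
  expect_equal(nom$n_coefficients, 1 + 1 + 1 + 9)
  # an all-equal stratified covariate is dropped with a warning
  d$bmi <- 27
  w <- capture_warnings(res <- quartile_nominal_fit(d, index = "y", snp = "g"))
  expect_match(w, "merging", all = FALSE)
  expect_match(w, "constant", all = FALSE)
  expect_equal(res$n_coefficients, 1 + 1 + 1 + 6)
})

test_that("forward and reverse models agree on strong effects", {
  set.seed(707)
  d <- make_direct_frame(1500, beta = 0.25)
  fwd <- fit_adjusted_model(d, index = "y", snp = "g")
  rev <- fit_reverse_model(d, snp = "g", index = "y")
  expect_identical(rev$direction, "genotype_on_index")
  expect_lt(fwd$p_value, 0.05)
  expect_lt(rev$p_value, 0.05)
  expect_equal(sign(fwd$beta), sign(rev$beta))
  # with identical rows and covariates the two directions share one partial
  # correlation, so the t-based p-values coincide; the sums of squares (and
  # hence power and lsn) do not, which is what separates the two reported
  # ranking variants
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fwd$ss_hypothesis, rev$ss_hypothesis)))
  expect_false(isTRUE(all.equal(fwd$ms_error, rev$ms_error)))
})

test_that("reverse model holds its nominal type-I error under the null", {
  set.seed(818)
  hits <- 0
  n_rep <- 300
  for (r in seq_len(n_rep)) {
    d <- make_direct_frame(200, beta = 0)
    hits <- hits + (fit_reverse_model(d, snp = "g", index = "y")$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.02)
  expect_lte(hits / n_rep, 0.09)
})

test_that("partial r with AIR: perfect dependence and independence limits", {
  set.seed(909)
  n <- 300
  base <- make_direct_frame(n)
  base$air <- rlnorm(n, log(1000), 0.5)
  # exact monotone transform with vanishing noise -> r near 1
  base$y <- base$air^1.3 * exp(rnorm(n, 0, 0.01))
  expect_gt(partial_r_with_air(base, "y"), 0.99)
  # independent index, large n -> |r| within sampling noise of 0
  set.seed(910)
  big <- make_direct_frame(2000)
  big$air <- rlnorm(2000, log(1000), 0.5)
  expect_lt(abs(partial_r_with_air(big, "y")), 0.08)
  expect_error(partial_r_with_air(base[1:5, ], "y"), "fewer than 10")
})

test_that("early-phase-driven cohort: early-window index tracks AIR better than HOMA-B", {
  cfg <- sim_config(n_subjects = 1350, frac_ivgtt = 0.25, seed = 117)
  sim <- simulate_cohort(cfg)
  ex <- apply_negative_exclusion(sim$cohort)
  f <- association_frame(ex$cohort, ex$panel)
  expect_gt(partial_r_with_air(f, "auc_ins_0_30"),
            partial_r_with_air(f, "homa_b"))
})
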