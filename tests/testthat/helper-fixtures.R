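# Shared fixtures: the published 12 x 6 lsn matrix with its parenthesised
# ranks and rank sums (frozen from the source tables), a brute-force OLS
# oracle, and small cohort builders.

ref_index_order <- c("homa_b", "insulin_30", "c_peptide_30", "igi1", "igi2",
                     "di_oral", "cir", "first_phase", "auc_ins_0_30",
                     "auc_ins_0_120", "auc_cp_0_30", "auc_cp_0_120")

ref_snp_order <- c("MTNR1B_rs10830963", "HHEX_rs7923837", "CDKAL1_rs7754840",
                   "TCF7L2_rs7903146", "WFS1_rs10010131", "KCNQ1_rs151290")

# published lsn values, rows in ref_index_order, columns in ref_snp_order
ref_lsn_matrix <- function() {
  m <- matrix(c(
    345, 4222, 34337, 2938, 2923, 42551,
    196,  587,   779, 4127, 2234,   852,
    241,  536,  2289, 4800, 1164,   657,
    201,  483,  1914, 2376, 1537,  1046,
    164,  527,   894, 3134, 2001,   797,
    288,  568,  1715, 3285, 2250,  1127,
    164,  447,  1487, 2098, 1824,  1075,
    208,  468,   936, 4951, 1976,   981,
    153,  456,   810, 2808, 1855,   803,
    478,  356,  4465, 1361, 5549,  1023,
    180,  500,  2993, 2580, 1112,   706,
    453,  338,  8127, 1109, 1276,   677), nrow = 12, byrow = TRUE,
    dimnames = list(ref_index_order, ref_snp_order))
  m
}

# published parenthesised ranks for the same cells
ref_rank_matrix <- function() {
  matrix(c(
    10, 12, 12,  7, 11, 12,
     5, 11,  1, 10,  9,  6,
     8,  9,  8, 11,  2,  1,
     6,  6,  7,  4,  4,  9,
     2,  8,  3,  8,  8,  4,
     9, 10,  6,  9, 10, 11,
     2,  3,  5,  3,  5, 10,
     7,  5,  4, 12,  7,  7,
     1,  4,  2,  6,  6,  5,
    12,  2, 10,  2, 12,  8,
     4,  7,  9,  5,  1,  3,
    11,  1, 11,  1,  3,  2), nrow = 12, byrow = TRUE,
    dimnames = list(ref_index_order, ref_snp_order))
}

ref_rank_sums <- c(homa_b = 64, insulin_30 = 42, c_peptide_30 = 39,
                   igi1 = 36, igi2 = 33, di_oral = 55, cir = 28,
                   first_phase = 42, auc_ins_0_30 = 24, auc_ins_0_120 = 46,
                   auc_cp_0_30 = 29, auc_cp_0_120 = 29)

ref_gsis_sums <- c(homa_b = 34, insulin_30 = 17, c_peptide_30 = 25,
                   igi1 = 19, igi2 = 13, di_oral = 25, cir = 10,
                   first_phase = 16, auc_ins_0_30 = 7, auc_ins_0_120 = 24,
                   auc_cp_0_30 = 20, auc_cp_0_120 = 23)

ref_isis_sums <- c(homa_b = 30, insulin_30 = 25, c_peptide_30 = 14,
                   igi1 = 17, igi2 = 20, di_oral = 30, cir = 18,
                   first_phase = 26, auc_ins_0_30 = 17, auc_ins_0_120 = 22,
                   auc_cp_0_30 = 9, auc_cp_0_120 = 6)

# indices starred as significantly better-ranked than HOMA-B
ref_starred <- c("auc_ins_0_30", "cir", "auc_cp_0_30", "auc_cp_0_120",
                 "igi2", "igi1", "insulin_30")

# brute-force normal-equation OLS: coefficients, SEs, partial F of term j
ols_oracle <- function(X, y, j) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df2 <- nrow(X) - ncol(X)
  mse <- sum(res^2) / df2
  se <- sqrt(diag(solve(XtX)) * mse)
  tval <- beta[j] / se[j]
  list(beta = drop(beta), se = se, f = tval^2, mse = mse, df2 = df2,
       p = 2 * pt(-abs(tval), df2))
}

# regression frame with a known per-allele effect on the log index and
# independent confounders (truth known exactly)
make_direct_frame <- function(n, beta = 0, maf = 0.3, sd_noise = 0.4) {
  g <- rbinom(n, 2, maf)
  data.frame(
    g = g,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = runif(n, 25, 65),
    bmi = rlnorm(n, log(27), 0.2),
    matsuda_isi = rlnorm(n, log(12), 0.4),
    y = exp(2 + beta * g + rnorm(n, 0, sd_noise)))
}

# minimal hand-made cohort rows with explicit OGTT values
make_cohort_row <- function(id, glc, ins, cpep, sex = "female", age = 40,
                            bmi = 26, geno = c(g1 = 1)) {
  row <- data.frame(subject_id = id, sex = sex, age = age, bmi = bmi,
                    stringsAsFactors = FALSE)
  row[paste0("glc_", c(0, 30, 60, 90, 120))] <- as.list(glc)
  row[paste0("ins_", c(0, 30, 60, 90, 120))] <- as.list(ins)
  row[paste0("cpep_", c(0, 30, 60, 90, 120))] <- as.list(cpep)
  for (nm in names(geno)) row[[nm]] <- geno[[nm]]
  row
}
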