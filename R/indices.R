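#' @keywords internal
"_PACKAGE"

# OGTT sampling grid is fixed; no interpolation of missing samples.
OGTT_MINUTES <- c(0L, 30L, 60L, 90L, 120L)
AIR_MINUTES <- c(0L, 2L, 4L, 6L, 8L, 10L)

# pmol/l per uIU/ml for immunoreactive insulin (WHO conversion); HOMA-B is
# defined on uIU/ml while all stored insulin concentrations are pmol/l.
PMOL_PER_UIU <- 6.0

#' Names of the twelve insulin secretion indices
#'
#' The secretion panel subject to the negative-value exclusion rule, in the
#' canonical reporting order. The Matsuda sensitivity index and the two
#' insulin clearances are companions of the panel, not members.
#'
#' @return Character vector of length 12.
#' @export
secretion_indices <- function() {
  c("homa_b", "insulin_30", "c_peptide_30", "igi1", "igi2", "di_oral",
    "cir", "first_phase", "auc_ins_0_30", "auc_ins_0_120",
    "auc_cp_0_30", "auc_cp_0_120")
}

as_series <- function(x, minutes, analyte = "series", subject = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(minutes)) {
    stop(sprintf("%s: expected samples at minutes {%s}, got %d columns",
                 analyte, paste(minutes, collapse = ","), ncol(x)),
         call. = FALSE)
  }
  bad <- !apply(is.finite(x), 1, all)
  if (any(bad)) {
    who <- if (is.null(subject)) which(bad)[1] else subject[bad][1]
    stop(sprintf("missing or non-finite %s sample for subject %s",
                 analyte, who), call. = FALSE)
  }
  x
}

#' Scaled trapezoid area under a five-point 0-120 min profile
#'
#' Computes \code{0.5 * (0.5*c0 + c30 + c60 + c90 + 0.5*c120)} for
#' concentration samples at minutes 0, 30, 60, 90 and 120. The 30-min
#' sampling interval is deliberately not multiplied in: only ratios of
#' these areas are ever interpreted, so the common scale cancels.
#'
#' @param x Numeric vector of length 5, or a matrix/data frame with five
#'   columns (one row per subject).
#' @param analyte,subject Optional labels used in error messages when a
#'   sample is missing.
#' @return Numeric vector of scaled areas, one per row of \code{x}.
#' @examples
#' trapezoid_auc(c(4, 8, 6, 5, 4))  # 11.5
#' @export
trapezoid_auc <- function(x, analyte = "series", subject = NULL) {
  x <- as_series(x, OGTT_MINUTES, analyte, subject)
  drop(x %*% c(0.25, 0.5, 0.5, 0.5, 0.25))
}

#' Fasting-state beta-cell function (HOMA-B)
#'
#' \code{20 * I0 / (G0 - 3.5)} with fasting insulin in uIU/ml and fasting
#' glucose in mmol/l. Stored insulin is pmol/l and is divided by
#' \code{pmol_per_uiu} first. A fasting glucose at or below 3.5 mmol/l
#' makes the denominator singular or negative; the result is then NA
#' (invalid), never an error.
#'
#' @param g0 Fasting glucose, mmol/l.
#' @param i0 Fasting insulin, pmol/l.
#' @param pmol_per_uiu Insulin unit conversion constant (default 6.0).
#' @return HOMA-B in U/mol (NA where undefined).
#' @export
homa_b <- function(g0, i0, pmol_per_uiu = PMOL_PER_UIU) {
  out <- 20 * (i0 / pmol_per_uiu) / (g0 - 3.5)
  out[g0 <= 3.5] <- NA_real_
  out
}

#' Insulinogenic indices and oral disposition index
#'
#' \code{igi1 = (I30 - I0) / (G30 - G0)}, \code{igi2 = (I30 - I0) / G30},
#' \code{di_oral = igi1 / I0}. Insulin in pmol/l, glucose in mmol/l.
#' Negative values are returned as-is (they drive the cohort-level
#' exclusion rule); singular denominators give NA.
#'
#' @param i0,i30 Insulin at 0 and 30 min, pmol/l.
#' @param g0,g30 Glucose at 0 and 30 min, mmol/l.
#' @return Numeric vector.
#' @export
igi1 <- function(i0, i30, g0, g30) {
  out <- (i30 - i0) / (g30 - g0)
  out[g30 == g0] <- NA_real_
  out
}

#' @rdname igi1
#' @export
igi2 <- function(i0, i30, g30) {
  out <- (i30 - i0) / g30
  out[g30 == 0] <- NA_real_
  out
}

#' @rdname igi1
#' @export
di_oral <- function(i0, i30, g0, g30) {
  out <- igi1(i0, i30, g0, g30) / i0
  out[i0 <= 0] <- NA_real_
  out
}

#' Corrected insulin response
#'
#' \code{100 * I30 / (G30 * (G30 - 3.89))}, l/mmol. A 30-min glucose at
#' 3.89 mmol/l is singular (NA); below it the index is negative and the
#' subject falls on the exclusion path.
#'
#' @param i30 Insulin at 30 min, pmol/l.
#' @param g30 Glucose at 30 min, mmol/l.
#' @export
cir <- function(i30, g30) {
  out <- 100 * i30 / (g30 * (g30 - 3.89))
  out[g30 == 3.89 | g30 == 0] <- NA_real_
  out
}

#' First-phase insulin secretion estimate
#'
#' Linear surrogate \code{1283 + 1.829*I30 - 138.7*G30 + 3.772*I0}
#' (insulin pmol/l, glucose mmol/l); may be negative.
#'
#' @param i0,i30 Insulin at 0 and 30 min, pmol/l.
#' @param g30 Glucose at 30 min, mmol/l.
#' @export
first_phase_stumvoll <- function(i0, i30, g30) {
  1283 + 1.829 * i30 - 138.7 * g30 + 3.772 * i0
}

#' AUC ratio of an analyte over glucose
#'
#' The 0-30 window uses the two-point sum form \code{(A0 + A30)/(G0 + G30)}
#' (equal to the two-point trapezoid ratio: the weights cancel). The 0-120
#' window uses \code{trapezoid_auc} for numerator and denominator.
#'
#' @param analyte Matrix (or length-5 vector) of insulin or C-peptide
#'   samples at minutes 0-120, pmol/l.
#' @param glucose Matching glucose samples, mmol/l.
#' @param window \code{"0-30"} or \code{"0-120"}.
#' @return Numeric vector; NA where the glucose denominator is not positive.
#' @export
auc_ratio <- function(analyte, glucose, window = c("0-30", "0-120")) {
  window <- match.arg(window)
  a <- as_series(analyte, OGTT_MINUTES, "analyte")
  g <- as_series(glucose, OGTT_MINUTES, "glucose")
  if (window == "0-30") {
    den <- g[, 1] + g[, 2]
    out <- (a[, 1] + a[, 2]) / den
  } else {
    den <- trapezoid_auc(g)
    out <- trapezoid_auc(a) / den
  }
  out[den <= 0] <- NA_real_
  out
}

#' Matsuda-DeFronzo composite insulin sensitivity index
#'
#' \code{10000 / sqrt(G0 * I0 * Gmean * Imean)} with the means taken as
#' unweighted arithmetic means of the five OGTT samples. Computed in
#' mmol/l and pmol/l; the resulting multiplicative constant relative to
#' the original mg/dl-uIU/ml form is absorbed by the intercept once the
#' index is log-transformed, so adjusted associations are unit-invariant.
#'
#' @param glucose Glucose samples at minutes 0-120, mmol/l (length-5
#'   vector or five-column matrix).
#' @param insulin Insulin samples, pmol/l, same shape.
#' @return Numeric vector; NA where any sample is not positive.
#' @export
matsuda_isi <- function(glucose, insulin) {
  g <- as_series(glucose, OGTT_MINUTES, "glucose")
  i <- as_series(insulin, OGTT_MINUTES, "insulin")
  arg <- g[, 1] * i[, 1] * rowMeans(g) * rowMeans(i)
  out <- 10000 / sqrt(arg)
  out[apply(g <= 0, 1, any) | apply(i <= 0, 1, any)] <- NA_real_
  out
}

#' Insulin clearance ratios
#'
#' Fasting: \code{CP0 / I0}. OGTT: ratio of the 0-120 min trapezoid areas
#' of C-peptide and insulin.
#'
#' @param c_peptide C-peptide samples at minutes 0-120, pmol/l.
#' @param insulin Insulin samples, pmol/l.
#' @param mode \code{"fasting"} or \code{"ogtt"}.
#' @export
insulin_clearance <- function(c_peptide, insulin, mode = c("fasting", "ogtt")) {
  mode <- match.arg(mode)
  cp <- as_series(c_peptide, OGTT_MINUTES, "c_peptide")
  i <- as_series(insulin, OGTT_MINUTES, "insulin")
  if (mode == "fasting") {
    den <- i[, 1]
    out <- cp[, 1] / den
  } else {
    den <- trapezoid_auc(i)
    out <- trapezoid_auc(cp) / den
  }
  out[den <= 0] <- NA_real_
  out
}

#' Acute insulin response from an IVGTT
#'
#' \code{0.5 * (0.5*I0 + I2 + I4 + I6 + I8 + 0.5*I10)} over the mandatory
#' post-bolus samples at minutes 0, 2, 4, 6, 8 and 10 (weights sum to 2.5,
#' so a constant profile c gives 2.5c).
#'
#' @param insulin Numeric vector of length 6, or six-column matrix, of
#'   IVGTT insulin samples at minutes 0, 2, 4, 6, 8, 10 (pmol/l).
#' @param subject Optional subject labels for error messages.
#' @return AIR in pmol/l.
#' @export
air_ivgtt <- function(insulin, subject = NULL) {
  x <- as_series_air(insulin, subject)
  drop(x %*% c(0.25, 0.5, 0.5, 0.5, 0.5, 0.25))
}

as_series_air <- function(x, subject = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(AIR_MINUTES)) {
    stop(sprintf("IVGTT insulin: need samples at minutes {%s}",
                 paste(AIR_MINUTES, collapse = ",")), call. = FALSE)
  }
  bad <- !apply(is.finite(x), 1, all)
  if (any(bad)) {
    who <- if (is.null(subject)) which(bad)[1] else subject[bad][1]
    stop(sprintf("missing or non-finite IVGTT insulin sample for subject %s",
                 who), call. = FALSE)
  }
  x
}

ogtt_cols <- function(prefix) paste0(prefix, "_", OGTT_MINUTES)

#' Compute the full index panel for a cohort
#'
#' Vectorised over subjects: takes a cohort data frame in the standard
#' schema (columns \code{glc_0..glc_120}, \code{ins_0..ins_120},
#' \code{cpep_0..cpep_120}) and returns one row per subject holding the
#' twelve secretion indices, the Matsuda sensitivity index, both insulin
#' clearances, a per-index validity flag set (non-finite = invalid) and
#' the \code{any_negative} exclusion flag. Subjects with incomplete OGTT
#' profiles get an \code{excluded_reason} instead of a crash.
#'
#' @param cohort Data frame in the standard cohort schema (see
#'   \code{\link{read_cohort}}).
#' @param pmol_per_uiu Insulin unit conversion used by HOMA-B.
#' @return Data frame: \code{subject_id}, the 15 values, logical
#'   \code{valid_*} columns for the twelve secretion indices,
#'   \code{any_negative} and \code{excluded_reason} (NA when retained).
#' @export
compute_panel <- function(cohort, pmol_per_uiu = PMOL_PER_UIU) {
  need <- c(ogtt_cols("glc"), ogtt_cols("ins"), ogtt_cols("cpep"))
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing OGTT columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- as.matrix(cohort[ogtt_cols("glc")])
  i <- as.matrix(cohort[ogtt_cols("ins")])
  cp <- as.matrix(cohort[ogtt_cols("cpep")])
  complete <- apply(is.finite(g), 1, all) & apply(is.finite(i), 1, all) &
    apply(is.finite(cp), 1, all) & apply(g > 0, 1, all)

  n <- nrow(cohort)
  panel <- data.frame(subject_id = as.character(cohort$subject_id),
                      stringsAsFactors = FALSE)
  val <- matrix(NA_real_, n, 15,
                dimnames = list(NULL, c(secretion_indices(), "matsuda_isi",
                                        "clearance_fasting", "clearance_ogtt")))
  if (any(complete)) {
    gg <- g[complete, , drop = FALSE]
    ic <- i[complete, , drop = FALSE]
    cpc <- cp[complete, , drop = FALSE]
    val[complete, "homa_b"] <- homa_b(gg[, 1], ic[, 1], pmol_per_uiu)
    val[complete, "insulin_30"] <- ic[, 2]
    val[complete, "c_peptide_30"] <- cpc[, 2]
    val[complete, "igi1"] <- igi1(ic[, 1], ic[, 2], gg[, 1], gg[, 2])
    val[complete, "igi2"] <- igi2(ic[, 1], ic[, 2], gg[, 2])
    val[complete, "di_oral"] <- di_oral(ic[, 1], ic[, 2], gg[, 1], gg[, 2])
    val[complete, "cir"] <- cir(ic[, 2], gg[, 2])
    val[complete, "first_phase"] <- first_phase_stumvoll(ic[, 1], ic[, 2], gg[, 2])
    val[complete, "auc_ins_0_30"] <- auc_ratio(ic, gg, "0-30")
    val[complete, "auc_ins_0_120"] <- auc_ratio(ic, gg, "0-120")
    val[complete, "auc_cp_0_30"] <- auc_ratio(cpc, gg, "0-30")
    val[complete, "auc_cp_0_120"] <- auc_ratio(cpc, gg, "0-120")
    val[complete, "matsuda_isi"] <- matsuda_isi(gg, ic)
    val[complete, "clearance_fasting"] <- insulin_clearance(cpc, ic, "fasting")
    val[complete, "clearance_ogtt"] <- insulin_clearance(cpc, ic, "ogtt")
  }
  panel <- cbind(panel, as.data.frame(val))

  sec <- val[, secretion_indices(), drop = FALSE]
  valid <- is.finite(sec)
  colnames(valid) <- paste0("valid_", secretion_indices())
  panel <- cbind(panel, as.data.frame(valid))
  panel$any_negative <- apply(sec, 1, function(r) any(is.finite(r) & r < 0))

  reason <- rep(NA_character_, n)
  reason[!complete] <- "incomplete_ogtt_profile"
  inval <- complete & !apply(valid, 1, all)
  reason[inval] <- "invalid_secretion_index"
  reason[complete & panel$any_negative] <- "negative_secretion_index"
  panel$excluded_reason <- reason
  panel
}

#' Exclude subjects with negative or undefined secretion indices
#'
#' A subject is removed when any of the twelve secretion indices is
#' negative, non-finite, or could not be computed from an incomplete
#' profile. Excluded subjects are reported by id with a reason, never
#' silently dropped.
#'
#' @param cohort Cohort data frame.
#' @param panel Optional precomputed result of \code{\link{compute_panel}}.
#' @return List with \code{cohort} (retained rows), \code{panel} (retained
#'   panel rows) and \code{excluded} (data frame of \code{subject_id},
#'   \code{reason}).
#' @export
apply_negative_exclusion <- function(cohort, panel = NULL) {
  if (is.null(panel)) panel <- compute_panel(cohort)
  drop_row <- !is.na(panel$excluded_reason)
  list(cohort = cohort[!drop_row, , drop = FALSE],
       panel = panel[!drop_row, , drop = FALSE],
       excluded = data.frame(subject_id = panel$subject_id[drop_row],
                             reason = panel$excluded_reason[drop_row],
                             stringsAsFactors = FALSE))
}

#' Glucose tolerance class from fasting and 2-h glucose
#'
#' ADA cutoffs, used for descriptive cohort summaries only: diabetes when
#' fasting glucose >= 7.0 or 2-h glucose >= 11.1 mmol/l; IFG when fasting
#' >= 5.6; IGT when 2-h >= 7.8; both -> "IFG+IGT"; otherwise NGT.
#'
#' @param g0 Fasting glucose, mmol/l.
#' @param g120 2-h glucose, mmol/l.
#' @return Factor with levels NGT, IFG, IGT, IFG+IGT, diabetes.
#' @export
classify_glucose_tolerance <- function(g0, g120) {
  out <- rep("NGT", length(g0))
  ifg <- g0 >= 5.6
  igt <- g120 >= 7.8
  out[ifg & !igt] <- "IFG"
  out[!ifg & igt] <- "IGT"
  out[ifg & igt] <- "IFG+IGT"
  out[g0 >= 7.0 | g120 >= 11.1] <- "diabetes"
  factor(out, levels = c("NGT", "IFG", "IGT", "IFG+IGT", "diabetes"))
}
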