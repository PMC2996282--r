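# Confounder-adjusted least-squares association of secretion indices with
# SNP genotypes. All continuous variables are log_e-transformed; genotype
# (0/1/2 minor-allele count) enters untransformed as an additive term; sex
# is a binary indicator (female = 0, male = 1).

DEFAULT_CONFOUNDERS <- c("sex", "age", "bmi", "matsuda_isi")

sex_indicator <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) stop("numeric sex must be 0/1", call. = FALSE)
    return(as.numeric(x))
  }
  x <- tolower(as.character(x))
  if (!all(x %in% c("female", "male", NA))) {
    stop("sex must be 'female'/'male' or 0/1", call. = FALSE)
  }
  as.numeric(x == "male")
}

# log_e with non-positive values treated as missing (they violate the
# positivity precondition and fall under listwise deletion).
log_pos <- function(x) {
  x <- as.numeric(x)
  x[!is.finite(x) | x <= 0] <- NA_real_
  log(x)
}

#' Split a covariate into sample quartiles
#'
#' Cuts at the 25/50/75 percentiles, lower-inclusive. Tied percentiles that
#' would make a quartile empty are merged with the neighbouring level, with
#' a warning.
#'
#' @param x Numeric vector.
#' @return Factor with up to four levels, lowest quartile first.
#' @export
cut_quartiles <- function(x) {
  br <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, names = FALSE)
  ub <- unique(br)
  if (length(ub) < length(br)) {
    warning("tied quartile boundaries: merging empty quartiles with neighbours",
            call. = FALSE)
  }
  if (length(ub) == 1) {
    f <- factor(rep("Q1", length(x)))
    f[is.na(x)] <- NA
    return(f)
  }
  cut(x, breaks = ub, include.lowest = TRUE, right = FALSE,
      labels = paste0("Q", seq_len(length(ub) - 1)))
}

build_design <- function(data, index, snp, confounders, covariate_mode) {
  df <- data.frame(row.names = seq_len(nrow(data)))
  df$.index <- log_pos(data[[index]])
  df$.geno <- as.numeric(data[[snp]])
  if (!all(df$.geno %in% c(0, 1, 2, NA))) {
    stop(sprintf("genotype column '%s' must hold 0/1/2 minor-allele counts", snp),
         call. = FALSE)
  }
  for (cv in confounders) {
    if (is.null(data[[cv]])) stop("unknown confounder column: ", cv, call. = FALSE)
    if (cv == "sex") {
      df$sex <- sex_indicator(data[[cv]])
    } else if (covariate_mode == "quartile_nominal") {
      f <- cut_quartiles(as.numeric(data[[cv]]))
      if (nlevels(droplevels(f)) < 2) {
        warning("covariate ", cv, " is constant after quartile merging; dropped",
                call. = FALSE)
      } else {
        df[[cv]] <- f
      }
    } else {
      df[[cv]] <- log_pos(data[[cv]])
    }
  }
  df
}

assoc_row <- function(fit, term, snp, index, direction, n_used, n_missing) {
  sm <- summary(fit)
  co <- sm$coefficients
  if (!term %in% rownames(co)) {
    stop("tested term dropped from the fit: ", term, call. = FALSE)
  }
  beta <- co[term, 1]
  se <- co[term, 2]
  tval <- beta / se
  df2 <- fit$df.residual
  mse <- sm$sigma^2
  f <- tval^2
  out <- data.frame(snp_id = snp, index_name = index, direction = direction,
                    n_used = n_used, n_missing = n_missing,
                    beta = beta, se = se,
                    p_value = 2 * stats::pt(-abs(tval), df2),
                    f_stat = f, ss_hypothesis = f * mse, ms_error = mse,
                    df1 = 1L, df2 = df2,
                    n_coefficients = n_used - df2,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Confounder-adjusted association of a secretion index with a SNP
#'
#' Ordinary least squares of the log_e-transformed index on the additive
#' genotype (minor-allele count 0/1/2) plus confounders: sex as a binary
#' indicator, the remaining confounders log_e-transformed (continuous mode)
#' or entered as 4-level quartile factors (nominal mode). Rows with any
#' missing required variable (or a non-positive value destined for the log)
#' are removed listwise; \code{n_used} and \code{n_missing} are reported.
#' The partial F, hypothesis sum of squares and error mean square of the
#' tested term are returned for downstream power and lsn computation.
#'
#' @param data Data frame holding the index column, genotype column and
#'   confounder columns (typically the retained cohort joined with its
#'   index panel, see \code{\link{association_frame}}).
#' @param index Name of the index column (tested continuous variable).
#' @param snp Name of the genotype column.
#' @param confounders Character vector of confounder column names; default
#'   sex, age, BMI and OGTT-derived insulin sensitivity.
#' @param covariate_mode \code{"continuous"} (log_e) or
#'   \code{"quartile_nominal"} for the non-sex confounders.
#' @param direction \code{"index_on_genotype"} (index is the dependent
#'   variable) or \code{"genotype_on_index"} (reverse model: genotype is
#'   the numeric dependent variable).
#' @return One-row data frame of class \code{assoc_result}: effect estimate
#'   \code{beta} (per minor allele on the log_e index in the forward
#'   direction), \code{se}, \code{p_value} (two-sided, partial F = t^2),
#'   \code{f_stat}, \code{ss_hypothesis}, \code{ms_error}, \code{df1},
#'   \code{df2}, \code{n_used}, \code{n_missing}, \code{n_coefficients}.
#' @export
fit_adjusted_model <- function(data, index, snp,
                               confounders = DEFAULT_CONFOUNDERS,
                               covariate_mode = c("continuous", "quartile_nominal"),
                               direction = c("index_on_genotype", "genotype_on_index")) {
  covariate_mode <- match.arg(covariate_mode)
  direction <- match.arg(direction)
  if (index == snp) stop("dependent and independent variables must differ", call. = FALSE)
  if (any(confounders %in% c(index, snp))) {
    stop("confounders must exclude the tested variables", call. = FALSE)
  }
  df <- build_design(data, index, snp, confounders, covariate_mode)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  n_used <- nrow(df)
  n_missing <- length(keep) - n_used

  rhs <- setdiff(names(df), c(".index", ".geno"))
  if (direction == "index_on_genotype") {
    form <- stats::reformulate(c(".geno", rhs), response = ".index")
    term <- ".geno"
  } else {
    form <- stats::reformulate(c(".index", rhs), response = ".geno")
    term <- ".index"
  }
  mm <- stats::model.matrix(form, df)
  if (n_used <= ncol(mm)) {
    stop(sprintf("only %d usable rows for %d coefficients (%s ~ %s)",
                 n_used, ncol(mm), index, snp), call. = FALSE)
  }
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    alias <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(alias, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(form, data = df)
  assoc_row(fit, term, snp, index, direction, n_used, n_missing)
}

#' @rdname fit_adjusted_model
#' @export
fit_reverse_model <- function(data, snp, index,
                              confounders = DEFAULT_CONFOUNDERS,
                              covariate_mode = "continuous") {
  fit_adjusted_model(data, index, snp, confounders, covariate_mode,
                     direction = "genotype_on_index")
}

#' @rdname fit_adjusted_model
#' @export
quartile_nominal_fit <- function(data, index, snp,
                                 confounders = DEFAULT_CONFOUNDERS,
                                 direction = "index_on_genotype") {
  fit_adjusted_model(data, index, snp, confounders,
                     covariate_mode = "quartile_nominal", direction = direction)
}

#' Assemble the analysis frame for association fitting
#'
#' Joins a (retained) cohort's covariates and genotype columns with its
#' index panel by \code{subject_id}, and, when IVGTT insulin columns
#' \code{ivgtt_ins_0 ... ivgtt_ins_10} are present, appends the acute
#' insulin response as an \code{air} column (NA outside the IVGTT subset).
#'
#' @param cohort Cohort data frame (after exclusion).
#' @param panel Matching result of \code{\link{compute_panel}}.
#' @param snps Genotype column names to carry over (default: every cohort
#'   column not part of the standard schema).
#' @return Data frame ready for \code{\link{fit_adjusted_model}}.
#' @export
association_frame <- function(cohort, panel, snps = NULL) {
  if (!identical(as.character(cohort$subject_id), panel$subject_id)) {
    panel <- panel[match(as.character(cohort$subject_id), panel$subject_id), ]
  }
  ivgtt_cols <- paste0("ivgtt_ins_", AIR_MINUTES)
  if (is.null(snps)) {
    known <- c("subject_id", "sex", "age", "bmi",
               ogtt_cols("glc"), ogtt_cols("ins"), ogtt_cols("cpep"),
               grep("^ivgtt_", names(cohort), value = TRUE))
    snps <- setdiff(names(cohort), known)
  }
  out <- cbind(cohort[c("subject_id", "sex", "age", "bmi", snps)],
               panel[setdiff(names(panel), "subject_id")])
  if (all(ivgtt_cols %in% names(cohort))) {
    iv <- as.matrix(cohort[ivgtt_cols])
    has <- apply(is.finite(iv), 1, all)
    air <- rep(NA_real_, nrow(cohort))
    if (any(has)) air[has] <- air_ivgtt(iv[has, , drop = FALSE])
    out$air <- air
  }
  out
}

#' Adjusted partial correlation of an index with IVGTT-derived AIR
#'
#' Fits log_e(AIR) on the log_e index plus the confounders over the IVGTT
#' subset and returns \code{sign(beta) * sqrt(partial R^2)} of the index
#' term, where partial R^2 = SSH / (SSH + SSE).
#'
#' @param data Data frame with an \code{air} column (NA outside the IVGTT
#'   subset), the index column and the confounders.
#' @param index Name of the index column.
#' @param confounders As in \code{\link{fit_adjusted_model}}.
#' @return Signed partial correlation (scalar).
#' @export
partial_r_with_air <- function(data, index, confounders = DEFAULT_CONFOUNDERS) {
  if (is.null(data$air)) stop("data must contain an 'air' column", call. = FALSE)
  df <- data.frame(.y = log_pos(data$air), .x = log_pos(data[[index]]))
  for (cv in confounders) {
    if (is.null(data[[cv]])) stop("unknown confounder column: ", cv, call. = FALSE)
    df[[cv]] <- if (cv == "sex") sex_indicator(data[[cv]]) else log_pos(data[[cv]])
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10) stop("fewer than 10 usable IVGTT subjects", call. = FALSE)
  form <- stats::reformulate(c(".x", confounders), response = ".y")
  fit <- stats::lm(form, data = df)
  co <- summary(fit)$coefficients
  tval <- co[".x", 1] / co[".x", 2]
  df2 <- fit$df.residual
  # SSH/(SSH+SSE) = t^2/(t^2 + df2) since SSH = t^2 * MSE and SSE = df2 * MSE
  sign(tval) * sqrt(tval^2 / (tval^2 + df2))
}
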