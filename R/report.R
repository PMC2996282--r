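# Pipeline orchestration: cohort I/O, full simulate/load -> indices ->
# exclusion -> association -> power/lsn -> ranking run, and a rank-only
# entry point that consumes a precomputed lsn matrix directly.

COHORT_REQUIRED <- function() {
  c("subject_id", "sex", "age", "bmi",
    ogtt_cols("glc"), ogtt_cols("ins"), ogtt_cols("cpep"))
}

#' Read a cohort TSV
#'
#' Strict reader for the standard schema: required columns
#' \code{subject_id, sex, age, bmi}, the fifteen OGTT columns
#' \code{glc_0..glc_120, ins_0..ins_120, cpep_0..cpep_120}, optional
#' \code{ivgtt_ins_*} columns, and one 0/1/2 column per SNP (blank =
#' missing). Violations raise errors naming the offending column or
#' subject.
#'
#' @param path TSV file with a header row.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(COHORT_REQUIRED(), names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- setdiff(names(df), c("subject_id", "sex"))
  for (cl in numeric_cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(v2))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' in column %s, data row %d",
                     v[bad[1]], cl, bad[1]), call. = FALSE)
      }
      df[[cl]] <- v2
    }
  }
  sex_indicator(df$sex)  # validates coding
  geno_cols <- setdiff(names(df), c(COHORT_REQUIRED(),
                                    grep("^ivgtt_", names(df), value = TRUE)))
  for (cl in geno_cols) {
    v <- df[[cl]]
    bad <- which(!is.na(v) & !v %in% c(0, 1, 2))
    if (length(bad)) {
      stop(sprintf("genotype column %s has value %s (subject %s); must be 0/1/2",
                   cl, v[bad[1]], df$subject_id[bad[1]]), call. = FALSE)
    }
  }
  df
}

#' Write a table as TSV
#'
#' Plain tab-separated output, no quoting, no row names;
#' \code{read_cohort(write_cohort(x))} round-trips a cohort.
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
write_cohort <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published reference lsn matrix for six risk SNPs
#'
#' The 12 x 6 least-significant-number matrix for the twelve secretion
#' indices against six confirmed type-2-diabetes risk SNPs (three acting
#' on glucose-stimulated secretion, three on the incretin axis), as
#' reported for a large European risk cohort (N = 1347 after exclusions).
#' Shipped so the rank-aggregation layer can be exercised and reproduced
#' without subject-level data.
#'
#' @return Numeric matrix (rows = indices, columns = SNPs) with a
#'   \code{subsets} attribute naming the GSIS and ISIS SNP triplets.
#' @export
reference_lsn <- function() {
  path <- system.file("extdata", "reference_lsn.tsv", package = "secrank")
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$index
  attr(m, "subsets") <- list(GSIS = colnames(m)[1:3], ISIS = colnames(m)[4:6])
  m
}

#' Rank-only pipeline entry point
#'
#' Runs the rank-aggregation layer on a precomputed (index x SNP) lsn
#' matrix: per-SNP competition ranks, rank sums per subset, final index
#' ordering and Wilcoxon comparison against the reference index.
#'
#' @param lsn_matrix Numeric matrix with index rownames and SNP colnames;
#'   defaults to the shipped \code{\link{reference_lsn}} matrix.
#' @param subsets Named list of SNP subsets; defaults to the matrix's
#'   \code{subsets} attribute, if any.
#' @param reference Reference index for the Wilcoxon comparison.
#' @param wilcoxon_method \code{"exact"} or \code{"normal"}.
#' @return A \code{\link{build_rank_table}} object.
#' @export
rank_only <- function(lsn_matrix = reference_lsn(), subsets = NULL,
                      reference = "homa_b", wilcoxon_method = "exact") {
  if (is.null(subsets)) subsets <- attr(lsn_matrix, "subsets")
  build_rank_table(lsn_matrix, subsets = subsets, reference = reference,
                   wilcoxon_method = wilcoxon_method)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> index panel -> negative-value exclusion -> adjusted
#' association per (index, SNP) -> post-hoc power and lsn -> rank table.
#' Deterministic for a fixed cohort (or simulation config with seed).
#'
#' @param cohort Cohort data frame (e.g. from \code{\link{read_cohort}});
#'   if NULL, one is simulated from \code{config}.
#' @param config \code{\link{sim_config}} used when \code{cohort} is NULL.
#' @param snps Genotype column names to test (default: auto-detected).
#' @param indices Index columns to test (default the twelve secretion
#'   indices).
#' @param subsets Named SNP subsets for rank sums (default: GSIS/ISIS
#'   split of the simulated panel when recognisable).
#' @param reference Reference index for the Wilcoxon comparison.
#' @param alpha Significance level for power and lsn.
#' @param confounders,covariate_mode,direction Passed to
#'   \code{\link{fit_adjusted_model}}.
#' @param wilcoxon_method Passed to \code{\link{build_rank_table}}.
#' @param outdir Optional directory; when given, writes
#'   \code{association.tsv} (per-pair statistics incl. power/lsn/rank),
#'   \code{ranking.tsv}, \code{exclusions.tsv}, \code{air_correlation.tsv}
#'   (when IVGTT data are present) and \code{manifest.json}.
#' @return List of class \code{secrank_run}: \code{association} (data
#'   frame), \code{rank_table}, \code{air} (data frame or NULL),
#'   \code{excluded}, \code{manifest}.
#' @export
run_pipeline <- function(cohort = NULL, config = NULL, snps = NULL,
                         indices = secretion_indices(), subsets = NULL,
                         reference = "homa_b", alpha = 0.05,
                         confounders = DEFAULT_CONFOUNDERS,
                         covariate_mode = "continuous",
                         direction = "index_on_genotype",
                         wilcoxon_method = "exact", outdir = NULL) {
  if (is.null(cohort)) {
    if (is.null(config)) stop("need a cohort or a sim_config", call. = FALSE)
    sim <- simulate_cohort(config)
    cohort <- sim$cohort
    if (is.null(snps)) snps <- vapply(config$snps, `[[`, "", "snp_id")
    if (is.null(subsets)) {
      routes <- vapply(config$snps, `[[`, "", "route")
      ids <- vapply(config$snps, `[[`, "", "snp_id")
      subsets <- list()
      if (any(routes == "early_phase")) subsets$GSIS <- ids[routes == "early_phase"]
      if (any(routes == "incretin_phase")) subsets$ISIS <- ids[routes == "incretin_phase"]
      if (!length(subsets)) subsets <- NULL
    }
  }
  if (is.null(snps)) {
    known <- c(COHORT_REQUIRED(), grep("^ivgtt_", names(cohort), value = TRUE))
    snps <- setdiff(names(cohort), known)
  }
  panel <- compute_panel(cohort)
  excl <- apply_negative_exclusion(cohort, panel)
  frame <- association_frame(excl$cohort, excl$panel, snps = snps)

  rows <- list()
  for (ix in indices) {
    for (sp in snps) {
      rows[[paste(ix, sp)]] <- fit_adjusted_model(
        frame, index = ix, snp = sp, confounders = confounders,
        covariate_mode = covariate_mode, direction = direction)
    }
  }
  assoc <- add_power_lsn(do.call(rbind, rows), alpha = alpha)
  row.names(assoc) <- NULL

  lsn_matrix <- matrix(assoc$lsn,
                       nrow = length(indices), ncol = length(snps),
                       byrow = TRUE, dimnames = list(indices, snps))
  rt <- build_rank_table(lsn_matrix, subsets = subsets,
                         reference = if (reference %in% indices) reference else NULL,
                         wilcoxon_method = wilcoxon_method)
  assoc$rank <- as.integer(t(rt$rank_matrix)[cbind(
    match(assoc$snp_id, snps), match(assoc$index_name, indices))])

  air_tab <- NULL
  if (!is.null(frame$air) && sum(is.finite(frame$air)) >= 10) {
    air_tab <- data.frame(index = indices,
                          r = vapply(indices, function(ix)
                            partial_r_with_air(frame, ix, confounders), 0),
                          n = sum(is.finite(frame$air)),
                          stringsAsFactors = FALSE, row.names = NULL)
    air_tab <- air_tab[order(-air_tab$r), ]
  }

  manifest <- list(n_input = nrow(cohort), n_excluded = nrow(excl$excluded),
                   n_retained = nrow(excl$cohort), snps = snps,
                   indices = indices, alpha = alpha,
                   covariate_mode = covariate_mode, direction = direction,
                   reference = reference, wilcoxon_method = wilcoxon_method,
                   package_version = as.character(utils::packageVersion("secrank")))
  out <- structure(list(association = assoc, rank_table = rt, air = air_tab,
                        excluded = excl$excluded, manifest = manifest),
                   class = "secrank_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$association, file.path(outdir, "association.tsv"))
  rank_rows <- do.call(rbind, lapply(names(run$rank_table$final), function(s) {
    tab <- run$rank_table$final[[s]]
    tab$subset <- s
    if (!is.null(run$rank_table$wilcoxon)) {
      w <- run$rank_table$wilcoxon[[s]]
      tab$wilcoxon_p_vs_ref <- w$p_value[match(tab$index, w$index)]
      tab$exploratory <- w$exploratory[match(tab$index, w$index)]
    }
    tab
  }))
  write_cohort(rank_rows, file.path(outdir, "ranking.tsv"))
  write_cohort(run$excluded, file.path(outdir, "exclusions.tsv"))
  if (!is.null(run$air)) {
    write_cohort(run$air, file.path(outdir, "air_correlation.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.secrank_run <- function(x, ...) {
  cat("secrank pipeline run:", x$manifest$n_retained, "subjects retained (",
      x$manifest$n_excluded, "excluded ),",
      length(x$manifest$snps), "SNPs x", length(x$manifest$indices), "indices\n")
  print(x$rank_table)
  invisible(x)
}
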