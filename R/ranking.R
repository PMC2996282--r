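# lsn-based rank aggregation of secretion indices over SNP panels, with
# exact Wilcoxon rank-sum comparison against a reference index.

#' Competition ranks of lsn values within one SNP column
#'
#' Ascending competition ranking: the smallest lsn (the most powerful
#' index) gets rank 1; ties share the minimum rank and the following ranks
#' are skipped.
#'
#' @param lsn_column Numeric vector of finite positive lsn values.
#' @return Integer ranks.
#' @export
rank_by_lsn <- function(lsn_column) {
  if (!all(is.finite(lsn_column) & lsn_column > 0)) {
    stop("lsn values must be finite and positive", call. = FALSE)
  }
  as.integer(rank(lsn_column, ties.method = "min"))
}

#' Exact two-sided Wilcoxon rank-sum p-value by complete enumeration
#'
#' Pools the two samples, assigns mid-ranks to ties, and enumerates all
#' choose(na+nb, na) assignments of the pooled values to the first group.
#' The two-sided p-value is min(1, 2 * min of the two tail probabilities),
#' each tail including the observed rank sum. Exact in the presence of
#' ties (unlike the classical tables); intended for small samples
#' (na, nb <= 12).
#'
#' @param a,b Numeric vectors (e.g. two indices' per-SNP ranks).
#' @return Two-sided p-value.
#' @export
wilcoxon_exact <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty input", call. = FALSE)
  pooled <- c(a, b)
  if (choose(length(pooled), length(a)) > 5e6) {
    stop("samples too large for complete enumeration", call. = FALSE)
  }
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  w_all <- colSums(matrix(r[combs], nrow = na))
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

#' Two-sample Wilcoxon rank-sum p-value, exact or normal approximation
#'
#' \code{method = "exact"} calls \code{\link{wilcoxon_exact}}.
#' \code{method = "normal"} uses the tie-corrected normal approximation
#' with continuity correction, the convention of classical statistical
#' packages (the two can disagree near the significance boundary for tied
#' small samples; see the package vignette).
#'
#' @param a,b Numeric vectors.
#' @param method \code{"exact"} or \code{"normal"}.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, method = c("exact", "normal")) {
  method <- match.arg(method)
  if (method == "exact") return(wilcoxon_exact(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

#' Rank table: per-SNP lsn ranks, rank sums and final index ordering
#'
#' Converts a (index x SNP) lsn matrix into per-SNP competition ranks,
#' sums each index's ranks over named SNP subsets, ranks the indices by
#' rank sum within each subset (competition ranking again), and compares
#' each index's per-SNP ranks against a reference index with a Wilcoxon
#' rank-sum test. Subset Wilcoxon p-values over fewer SNPs than the full
#' panel are exploratory (small samples) and flagged as such.
#'
#' @param lsn_matrix Numeric matrix, rows = indices (rownames required),
#'   columns = SNPs (colnames required).
#' @param subsets Named list of character vectors of SNP ids; a subset
#'   named \code{ALL} covering every column is added if absent.
#' @param reference Index name the Wilcoxon comparison is made against
#'   (default \code{"homa_b"}; NULL to skip).
#' @param wilcoxon_method Passed to \code{\link{wilcoxon_rank_sum}}.
#' @return Object of class \code{rank_table}: list with \code{lsn_matrix},
#'   \code{rank_matrix}, \code{subsets}, \code{rank_sums} (index x subset
#'   matrix), \code{final} (per-subset data frames of index, rank_sum,
#'   rank) and \code{wilcoxon} (per-subset data frame of index, p_value,
#'   exploratory flag).
#' @export
build_rank_table <- function(lsn_matrix, subsets = NULL, reference = "homa_b",
                             wilcoxon_method = "exact") {
  lsn_matrix <- as.matrix(lsn_matrix)
  if (is.null(rownames(lsn_matrix)) || is.null(colnames(lsn_matrix))) {
    stop("lsn_matrix needs index rownames and SNP colnames", call. = FALSE)
  }
  if (is.null(subsets)) subsets <- list()
  if (!"ALL" %in% names(subsets)) {
    subsets <- c(list(ALL = colnames(lsn_matrix)), subsets)
  }
  for (s in names(subsets)) {
    bad <- setdiff(subsets[[s]], colnames(lsn_matrix))
    if (length(bad)) {
      stop("subset ", s, " references unknown SNPs: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  rank_matrix <- apply(lsn_matrix, 2, rank_by_lsn)
  rownames(rank_matrix) <- rownames(lsn_matrix)

  rank_sums <- sapply(subsets, function(s)
    rowSums(rank_matrix[, s, drop = FALSE]))
  final <- lapply(names(subsets), function(s) {
    rs <- rank_sums[, s]
    out <- data.frame(index = names(rs), rank_sum = as.integer(rs),
                      rank = as.integer(rank(rs, ties.method = "min")),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$rank, out$index), , drop = FALSE]
  })
  names(final) <- names(subsets)

  wilcoxon <- NULL
  if (!is.null(reference)) {
    if (!reference %in% rownames(rank_matrix)) {
      stop("unknown reference index: ", reference, call. = FALSE)
    }
    wilcoxon <- lapply(names(subsets), function(s) {
      cols <- subsets[[s]]
      ref <- rank_matrix[reference, cols]
      data.frame(index = rownames(rank_matrix),
                 p_value = vapply(rownames(rank_matrix), function(i)
                   wilcoxon_rank_sum(rank_matrix[i, cols], ref,
                                     method = wilcoxon_method), 0),
                 exploratory = length(cols) < ncol(rank_matrix),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    names(wilcoxon) <- names(subsets)
  }
  structure(list(lsn_matrix = lsn_matrix, rank_matrix = rank_matrix,
                 subsets = subsets, rank_sums = rank_sums, final = final,
                 reference = reference, wilcoxon = wilcoxon),
            class = "rank_table")
}

#' Sum of an index's per-SNP ranks over a SNP subset
#'
#' @param rank_table A \code{rank_table} from \code{\link{build_rank_table}}.
#' @param index Index name.
#' @param snp_subset Character vector of SNP ids (empty subset sums to 0),
#'   or the name of a subset stored in the table.
#' @return Integer rank sum.
#' @export
rank_sum <- function(rank_table, index, snp_subset) {
  rm_ <- rank_table$rank_matrix
  if (!index %in% rownames(rm_)) stop("unknown index: ", index, call. = FALSE)
  if (length(snp_subset) == 1 && snp_subset %in% names(rank_table$subsets)) {
    snp_subset <- rank_table$subsets[[snp_subset]]
  }
  bad <- setdiff(snp_subset, colnames(rm_))
  if (length(bad)) stop("unknown SNPs: ", paste(bad, collapse = ", "), call. = FALSE)
  as.integer(sum(rm_[index, snp_subset]))
}

#' Final competition ranking of indices by rank sum
#'
#' @param rank_sums Named numeric vector, one rank sum per index.
#' @return Data frame of index, rank_sum and competition rank, ordered
#'   best first.
#' @export
final_ranking <- function(rank_sums) {
  out <- data.frame(index = names(rank_sums),
                    rank_sum = as.integer(rank_sums),
                    rank = as.integer(rank(rank_sums, ties.method = "min")),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank, out$index), , drop = FALSE]
}

#' @export
print.rank_table <- function(x, ...) {
  cat("lsn rank table:", nrow(x$lsn_matrix), "indices x",
      ncol(x$lsn_matrix), "SNPs\n")
  for (s in names(x$final)) {
    cat("\nsubset", s, "(", paste(x$subsets[[s]], collapse = ", "), ")\n")
    tab <- x$final[[s]]
    if (!is.null(x$wilcoxon)) {
      tab$p_vs_ref <- signif(x$wilcoxon[[s]]$p_value[
        match(tab$index, x$wilcoxon[[s]]$index)], 3)
    }
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
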