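#!/usr/bin/env Rscript
# Thin command-line wrapper over the secrank package.
#
#   Rscript scripts/secrank.R simulate  --n 1350 --seed 1 --out cohort.tsv
#   Rscript scripts/secrank.R all       --cohort cohort.tsv --outdir results/
#   Rscript scripts/secrank.R all       --n 1350 --seed 1 --outdir results/
#   Rscript scripts/secrank.R rank-only --outdir results/   (published lsn matrix)

suppressPackageStartupMessages({
  library(secrank)
  library(optparse)
})

usage <- function() {
  cat("usage: secrank.R <simulate|all|rank-only> [options]\n")
  quit(status = 1)
}

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) usage()
cmd <- argv[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 1350),
  make_option("--seed", type = "integer", default = 1),
  make_option("--cohort", type = "character", default = NULL),
  make_option("--out", type = "character", default = "cohort.tsv"),
  make_option("--truth", type = "character", default = NULL),
  make_option("--outdir", type = "character", default = "secrank_out"),
  make_option("--reference", type = "character", default = "homa_b"),
  make_option("--alpha", type = "double", default = 0.05),
  make_option("--covariate-mode", type = "character", default = "continuous",
              dest = "covariate_mode"),
  make_option("--wilcoxon", type = "character", default = "exact")
)), args = argv[-1])

if (cmd == "simulate") {
  cfg <- sim_config(n_subjects = opts$n, seed = opts$seed)
  sim <- simulate_cohort(cfg)
  write_cohort(sim$cohort, opts$out)
  if (!is.null(opts$truth)) {
    jsonlite::write_json(sim$truth, opts$truth, auto_unbox = TRUE,
                         dataframe = "columns", pretty = TRUE)
  }
  cat("wrote", opts$out, "(", nrow(sim$cohort), "subjects )\n")
} else if (cmd == "all") {
  cohort <- if (!is.null(opts$cohort)) read_cohort(opts$cohort) else NULL
  cfg <- if (is.null(cohort)) sim_config(n_subjects = opts$n, seed = opts$seed)
         else NULL
  run <- run_pipeline(cohort = cohort, config = cfg, alpha = opts$alpha,
                      reference = opts$reference,
                      covariate_mode = opts$covariate_mode,
                      wilcoxon_method = opts$wilcoxon, outdir = opts$outdir)
  print(run)
  cat("tables written to", opts$outdir, "\n")
} else if (cmd == "rank-only") {
  rt <- rank_only(reference = opts$reference, wilcoxon_method = opts$wilcoxon)
  print(rt)
  dir.create(opts$outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(names(rt$final), function(s) {
    x <- rt$final[[s]]; x$subset <- s
    w <- rt$wilcoxon[[s]]
    x$wilcoxon_p_vs_ref <- w$p_value[match(x$index, w$index)]
    x
  }))
  write_cohort(tab, file.path(opts$outdir, "ranking.tsv"))
  cat("ranking written to", file.path(opts$outdir, "ranking.tsv"), "\n")
} else usage()
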