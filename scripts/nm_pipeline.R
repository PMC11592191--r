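#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/nm_pipeline.R simulate --out sim [--seed 1] [--conditions control,BDNF] [--no-cclamp]
#   Rscript scripts/nm_pipeline.R analyze  --in sim --out tables
#   Rscript scripts/nm_pipeline.R stats    --in tables/features.csv --out report [--metrics a,b]

suppressMessages(library(nmephys))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: nm_pipeline.R <simulate|analyze|stats> [options]", call. = FALSE)
}
cmd <- args[1]
opt <- list(seed = 1L, conditions = "control,BDNF", cclamp = TRUE,
            metrics = "g_lva_m42.5_nS,po_hva_m2.5,g_hva_p17.5_nS",
            `in` = NULL, out = NULL, verbose = TRUE)
i <- 2L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--no-cclamp") { opt$cclamp <- FALSE; i <- i + 1L }
  else if (a == "--quiet") { opt$verbose <- FALSE; i <- i + 1L }
  else if (grepl("^--", a)) { opt[[sub("^--", "", a)]] <- args[i + 1L]; i <- i + 2L }
  else stop(sprintf("unknown argument: %s", a), call. = FALSE)
}
if (is.null(opt$out)) stop("--out is required", call. = FALSE)

status <- tryCatch({
  if (cmd == "simulate") {
    run_simulate(strsplit(opt$conditions, ",")[[1]], out = opt$out,
                 seed = as.integer(opt$seed),
                 include_cclamp = isTRUE(opt$cclamp),
                 quiet = !opt$verbose)
  } else if (cmd == "analyze") {
    if (is.null(opt$`in`)) stop("--in is required", call. = FALSE)
    run_analyze(opt$`in`, out = opt$out, quiet = !opt$verbose)
  } else if (cmd == "stats") {
    if (is.null(opt$`in`)) stop("--in is required", call. = FALSE)
    run_stats(opt$`in`, out = opt$out,
              metrics = strsplit(opt$metrics, ",")[[1]],
              quiet = !opt$verbose)
  } else {
    stop(sprintf("unknown command: %s", cmd), call. = FALSE)
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
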