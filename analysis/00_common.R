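# Shared helpers for the analysis drivers: dataset caching under scratch/
# and output locations under results/.

suppressPackageStartupMessages(library(piswarm))

DATA_DIR <- "scratch/datasets"
RESULTS_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# simulate a shipped config once and cache the bundle for later steps
get_bundle <- function(name) {
  path <- file.path(DATA_DIR, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  message("simulating dataset '", name, "' ...")
  bundle <- simulate_dataset(sim_config(name))
  saveRDS(bundle, path)
  bundle
}

get_pool <- function(bundle, name) {
  path <- file.path(DATA_DIR, paste0(name, "_pool.rds"))
  if (file.exists(path)) return(readRDS(path))
  pool <- collapse_reads(bundle$reads)
  saveRDS(pool, path)
  pool
}

save_table <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  write_tsv_table(x, path)
  message("wrote ", path)
}
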