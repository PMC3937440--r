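# Shared fixtures: small cohorts for unit tests and the cached full-size
# cohorts used by the acceptance criteria (generated once per test run).

.cohort_cache <- new.env(parent = emptyenv())

# full paper_defaults cohort at a given seed, pipeline output cached
acceptance_gene_table <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("dga_acc_", seed))
    generate_cohort(paper_defaults(), dir, seed = seed)
    .cohort_cache[[key]] <-
      run_pipeline(dir, quiet = TRUE)$gene_table
    unlink(dir, recursive = TRUE)
  }
  .cohort_cache[[key]]
}

small_cohort <- function(n = 200, seed = 42, config = NULL) {
  cfg <- if (is.null(config)) small_profile() else config
  cfg$n_genes <- as.integer(n)
  dir <- file.path(tempdir(), paste0("dga_small_", seed, "_", n,
                                     "_", abs(sum(utf8ToInt(digest_cfg(cfg))))))
  if (!dir.exists(dir)) generate_cohort(cfg, dir, seed = seed)
  dir
}

digest_cfg <- function(cfg) {
  paste(substr(paste(deparse(cfg), collapse = ""), 1, 50),
        nchar(paste(deparse(cfg), collapse = "")))
}

class_mean <- function(gt, col, cl) mean(gt[[col]][gt$disease_class == cl],
                                         na.rm = TRUE)

pct_excess <- function(gt, col, cl)
  100 * (class_mean(gt, col, cl) / class_mean(gt, col, "none") - 1)
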