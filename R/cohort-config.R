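## Synthetic-cohort configuration.
##
## The default (`paper_defaults()`) encodes the observed effect sizes the
## pipeline is expected to recover: disease genes ~28% (Mendelian) and
## ~44% (GWAS) longer in total CDS, ~50% longer in average CDS, ~5% lower
## intron divergence, 11%/17% more intronic SNPs, and mean minor allele
## frequencies shifted +10%/-10%; cohort-level targets are a CDS-length CV
## of 0.78, an intron-CDS length correlation of r = 0.36 and a mean intron
## divergence of 1.05%. The shipped correlation and baseline-rate constants
## were produced by calibrate_generator() (see that function's docs).

#' Names of the 8 genomic covariates
#'
#' Column order is fixed and matches the standardized-regression factor
#' list used throughout the report.
#' @return character vector of length 8.
#' @export
dga_covariate_names <- function() {
  c("GC content", "Nucleosome occupancy", "Female recombination rate",
    "Male recombination rate", "Germ-line expression", "Replication time",
    "Distance to telomere", "Distance to centromere")
}

#' Build a synthetic-cohort configuration
#'
#' All pieces have defaults from [paper_defaults()]; pass replacements for
#' any component. See the package vignette for the generative model and the
#' meaning and units of each parameter.
#'
#' @param n_genes number of genes to generate.
#' @param class_fractions named fractions for `none`, `mendelian`, `gwas`
#'   (must sum to 1).
#' @param length_model lognormal location/scale for total CDS and total
#'   intron length (bp), per-class multiplicative effects, the average/total
#'   CDS ratio model and the log-scale intron-CDS correlation.
#' @param covariate_model means, SDs and correlation matrix of the 8
#'   covariates.
#' @param rate_model baseline per-lineage substitution rate
#'   (substitutions/site), standardized-covariate coefficient vector on the
#'   log rate, CpG rate multiplier `kappa`, per-class divergence
#'   multipliers.
#' @param diversity_model per-class SNP-density multipliers, baseline
#'   diversity/divergence ratio, genealogy dispersion (squared CV of the
#'   gamma genealogy factor), and the truncated-Beta MAF model (shape plus
#'   per-class means in (0, 0.5)).
#' @param seq_model intron GC fraction, CpG dinucleotide density and CDS GC
#'   fraction of the simulated sequences.
#' @param seed integer seed stored with the config (CLI `--seed` overrides).
#' @return validated list of class `dga_config`.
#' @export
cohort_config <- function(n_genes = NULL, class_fractions = NULL,
                          length_model = NULL, covariate_model = NULL,
                          rate_model = NULL, diversity_model = NULL,
                          seq_model = NULL, seed = NULL) {
  cfg <- paper_defaults()
  repl <- list(n_genes = n_genes, class_fractions = class_fractions,
               length_model = length_model, covariate_model = covariate_model,
               rate_model = rate_model, diversity_model = diversity_model,
               seq_model = seq_model, seed = seed)
  for (nm in names(repl)) {
    if (is.null(repl[[nm]])) next
    if (is.list(cfg[[nm]]) && is.list(repl[[nm]])) {
      cfg[[nm]][names(repl[[nm]])] <- repl[[nm]]
    } else cfg[[nm]] <- repl[[nm]]
  }
  validate_config(cfg)
}

#' The calibrated default configuration
#'
#' Class fractions echo a 17,062 / 820 / 1,726 autosomal cohort. The total
#' CDS lognormal scale 0.6894 gives a within-class CV of
#' sqrt(exp(sigma^2)-1) = 0.78. `log_length_correlation` and
#' `baseline_rate` are calibration outputs pinning the cohort intron-CDS
#' length correlation to 0.36 and the cohort mean intron divergence to
#' 0.0105 (see [calibrate_generator()]). Intron lengths are scaled to a
#' ~5 kb mean so a 17,000-gene cohort stays desk-sized; the CpG density
#' (0.02 per dinucleotide) and kappa = 10 are conventional choices.
#'
#' @return a `dga_config` list.
#' @export
paper_defaults <- function() {
  cov_names <- dga_covariate_names()
  cfg <- list(
    n_genes = 17000L,
    class_fractions = c(none = 0.851, mendelian = 0.048, gwas = 0.101),
    length_model = list(
      # total CDS: mean 1500 bp, CV 0.78 (sigma chosen as sqrt(log(1+CV^2)))
      total_cds_meanlog = log(1500) - 0.6894^2 / 2,
      total_cds_sdlog = 0.6894,
      class_mult_total_cds = c(none = 1, mendelian = 1.28, gwas = 1.44),
      # average CDS is a Beta-distributed fraction of total CDS (see vignette);
      # ratio means per class are derived from these multipliers
      avg_ratio_base = 0.60,
      avg_ratio_precision = 10,
      class_mult_avg_cds = c(none = 1, mendelian = 1.50, gwas = 1.50),
      # total intron length: mean ~5 kb (desk-scaled; see vignette)
      intron_meanlog = log(5000) - 1.1^2 / 2,
      intron_sdlog = 1.1,
      class_mult_intron = c(none = 1, mendelian = 1, gwas = 1),
      # calibrated: natural-scale Pearson r(intron, total CDS) = 0.36
      log_length_correlation = 0.48384,
      introns_per_gene = 3       # mean of the (1 + Poisson) intron count
    ),
    covariate_model = list(
      names = cov_names,
      means = setNames(c(0.45, 0.50, 1.30, 0.90, 5.0, 0.0, 40, 60), cov_names),
      sds = setNames(c(0.07, 0.10, 0.90, 0.60, 2.0, 1.0, 25, 35), cov_names),
      correlation = diag(8)
    ),
    rate_model = list(
      # calibrated: cohort mean intron divergence = 0.0105
      baseline_rate = 0.0034836,
      # coefficients on the z-scored covariates in the log rate; signs follow
      # the observed standardized-regression column for intron divergence
      coefficients = setNames(0.7 * c(0.525, -0.396, -0.020, 0.202,
                                      -0.062, -0.132, -0.158, -0.018),
                              cov_names),
      cpg_multiplier = 10,
      class_mult_divergence = c(none = 1, mendelian = 0.95, gwas = 0.95)
    ),
    diversity_model = list(
      class_mult_snp_density = c(none = 1, mendelian = 1.11, gwas = 1.17),
      pi_over_div = 0.20,          # baseline diversity/divergence ratio
      genealogy_dispersion = 0.09, # squared CV of the gamma genealogy factor
      maf_shape = 0.8,
      maf_means = c(none = 0.10, mendelian = 0.11, gwas = 0.09)
    ),
    seq_model = list(intron_gc = 0.44, cpg_density = 0.02, cds_gc = 0.52),
    seed = 1L
  )
  structure(cfg, class = "dga_config")
}

#' Small-profile configuration for quick runs and CI
#'
#' 2,000 genes with shorter introns (~1.5 kb mean); all effect sizes as in
#' [paper_defaults()].
#' @return a `dga_config` list.
#' @export
small_profile <- function() {
  cfg <- paper_defaults()
  cfg$n_genes <- 2000L
  cfg$length_model$intron_meanlog <- log(1500) - 1.1^2 / 2
  validate_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the documented invariants (fractions sum to 1, positive scales,
#' `kappa >= 1`, MAF means in (0, 0.5), PSD covariate correlation, ...).
#' Errors name the offending field.
#'
#' @param cfg a config list.
#' @return the config, classed `dga_config`, invisibly usable downstream.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid config: ", field, " ", msg,
                                    call. = FALSE)
  if (!is.numeric(cfg$n_genes) || cfg$n_genes < 0 ||
      cfg$n_genes != round(cfg$n_genes))
    fail("n_genes", "must be a non-negative integer")
  cf <- cfg$class_fractions
  if (!all(c("none", "mendelian", "gwas") %in% names(cf)))
    fail("class_fractions", "must name none, mendelian, gwas")
  if (any(cf < 0)) fail("class_fractions", "must be non-negative")
  if (abs(sum(cf) - 1) > 1e-9) fail("class_fractions", "must sum to 1")
  lm <- cfg$length_model
  for (f in c("total_cds_sdlog", "intron_sdlog", "avg_ratio_precision"))
    if (lm[[f]] <= 0) fail(paste0("length_model$", f), "must be > 0")
  if (lm$avg_ratio_base <= 0 || lm$avg_ratio_base > 1)
    fail("length_model$avg_ratio_base", "must be in (0, 1]")
  if (abs(lm$log_length_correlation) > 1)
    fail("length_model$log_length_correlation", "must be in [-1, 1]")
  for (f in c("class_mult_total_cds", "class_mult_avg_cds", "class_mult_intron"))
    if (any(lm[[f]] <= 0)) fail(paste0("length_model$", f), "must be > 0")
  # realized mean average-CDS ratio per class must stay in (0, 1]
  ratio_means <- lm$avg_ratio_base * lm$class_mult_avg_cds /
    lm$class_mult_total_cds
  if (any(ratio_means <= 0 | ratio_means > 1))
    fail("length_model", paste("implies an average/total CDS ratio outside",
                               "(0, 1]; lower avg_ratio_base or the",
                               "class_mult_avg_cds/class_mult_total_cds ratio"))
  cm <- cfg$covariate_model
  if (length(cm$names) != 8L) fail("covariate_model$names", "must have 8 entries")
  if (!isTRUE(all.equal(cm$correlation, t(cm$correlation))))
    fail("covariate_model$correlation", "must be symmetric")
  ev <- eigen(cm$correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    fail("covariate_model$correlation", "must be positive semi-definite")
  if (any(cm$sds <= 0)) fail("covariate_model$sds", "must be > 0")
  rm_ <- cfg$rate_model
  if (rm_$baseline_rate <= 0 || rm_$baseline_rate >= 0.1)
    fail("rate_model$baseline_rate", "must be in (0, 0.1)")
  if (rm_$cpg_multiplier < 1) fail("rate_model$cpg_multiplier", "must be >= 1")
  if (any(rm_$class_mult_divergence <= 0))
    fail("rate_model$class_mult_divergence", "must be > 0")
  if (length(rm_$coefficients) != 8L)
    fail("rate_model$coefficients", "must have 8 entries")
  dm <- cfg$diversity_model
  if (any(dm$class_mult_snp_density <= 0))
    fail("diversity_model$class_mult_snp_density", "must be > 0")
  if (dm$pi_over_div <= 0) fail("diversity_model$pi_over_div", "must be > 0")
  if (dm$genealogy_dispersion < 0)
    fail("diversity_model$genealogy_dispersion", "must be >= 0")
  if (dm$maf_shape <= 0) fail("diversity_model$maf_shape", "must be > 0")
  if (any(dm$maf_means <= 0 | dm$maf_means >= 0.5))
    fail("diversity_model$maf_means", "must lie in (0, 0.5)")
  sm <- cfg$seq_model
  if (sm$intron_gc <= 0 || sm$intron_gc >= 1)
    fail("seq_model$intron_gc", "must be in (0, 1)")
  if (sm$cpg_density < 0 || sm$cpg_density > (sm$intron_gc / 2)^2 * 1.0001 + 0.25)
    fail("seq_model$cpg_density", "out of range")
  if (sm$cds_gc <= 0 || sm$cds_gc >= 1)
    fail("seq_model$cds_gc", "must be in (0, 1)")
  if (!is.numeric(cfg$seed)) fail("seed", "must be numeric")
  structure(cfg, class = "dga_config")
}

#' Read / write configurations as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a validated `dga_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml loses the matrix shape and named vectors; restore them
  cfg$class_fractions <- unlist(cfg$class_fractions)
  cfg$covariate_model$correlation <- matrix(
    unlist(cfg$covariate_model$correlation), nrow = 8, byrow = TRUE)
  cfg$covariate_model$means <- unlist(cfg$covariate_model$means)
  cfg$covariate_model$sds <- unlist(cfg$covariate_model$sds)
  cfg$covariate_model$names <- unlist(cfg$covariate_model$names)
  for (f in c("class_mult_total_cds", "class_mult_avg_cds", "class_mult_intron"))
    cfg$length_model[[f]] <- unlist(cfg$length_model[[f]])
  cfg$rate_model$coefficients <- unlist(cfg$rate_model$coefficients)
  cfg$rate_model$class_mult_divergence <-
    unlist(cfg$rate_model$class_mult_divergence)
  cfg$diversity_model$class_mult_snp_density <-
    unlist(cfg$diversity_model$class_mult_snp_density)
  cfg$diversity_model$maf_means <- unlist(cfg$diversity_model$maf_means)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a `dga_config`.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$covariate_model$correlation <-
    lapply(seq_len(nrow(out$covariate_model$correlation)),
           function(i) unname(out$covariate_model$correlation[i, ]))
  # yaml drops names on atomic vectors; store named vectors as maps
  listify <- function(x) {
    if (is.list(x)) return(lapply(x, listify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(lapply(out, listify), path)
  invisible(path)
}
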