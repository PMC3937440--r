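# The synthetic-cohort generator: configuration, samplers, sequence
# simulation, SNP placement, determinism, calibration.

test_that("config validation names the offending field", {
  expect_s3_class(paper_defaults(), "dga_config")
  expect_error(cohort_config(class_fractions = c(none = 0.5, mendelian = 0.2,
                                                 gwas = 0.2)),
               "class_fractions")
  expect_error(cohort_config(diversity_model = list(maf_means =
    c(none = 0.6, mendelian = 0.1, gwas = 0.1))), "maf_means")
  expect_error(cohort_config(rate_model = list(cpg_multiplier = 0.5)),
               "cpg_multiplier")
  bad_corr <- diag(8); bad_corr[1, 2] <- bad_corr[2, 1] <- 2
  expect_error(cohort_config(covariate_model = list(correlation = bad_corr)),
               "positive semi-definite")
  expect_error(cohort_config(length_model = list(total_cds_sdlog = -1)),
               "total_cds_sdlog")
})

test_that("sample_lengths realizes class multipliers and the log correlation", {
  set.seed(101)
  classes <- sample(rep(c("none", "mendelian", "gwas"), c(30000, 5000, 5000)))
  len <- sample_lengths(classes, paper_defaults()$length_model)
  m <- function(col, cl) mean(len[[col]][classes == cl])
  # multipliers on total CDS recovered within 3 SE
  r_mend <- m("total_cds_length", "mendelian") / m("total_cds_length", "none")
  r_gwas <- m("total_cds_length", "gwas") / m("total_cds_length", "none")
  se <- 0.78 * sqrt(1 / 5000 + 1 / 30000)
  expect_lt(abs(r_mend - 1.28), 3 * se * 1.28)
  expect_lt(abs(r_gwas - 1.44), 3 * se * 1.44)
  # average CDS multiplier 1.5 for both classes
  ra <- m("average_cds_length", "mendelian") / m("average_cds_length", "none")
  expect_lt(abs(ra - 1.50), 0.09)
  # within-class CV of total CDS follows the lognormal closed form
  cv <- sd(len$total_cds_length[classes == "none"]) /
    mean(len$total_cds_length[classes == "none"])
  expect_equal(cv, sqrt(exp(0.6894^2) - 1), tolerance = 0.03)
  # log-scale correlation matches the configured parameter
  lc <- cor(log(len$total_intron_length), log(len$total_cds_length))
  expect_equal(lc, paper_defaults()$length_model$log_length_correlation,
               tolerance = 0.02)
  # structural invariants
  expect_true(all(len$total_cds_length %% 3 == 0))
  expect_true(all(len$average_cds_length <= len$total_cds_length))
  expect_true(all(len$average_cds_length * len$n_transcripts >=
                  len$total_cds_length))
  # empty class: nothing emitted
  expect_equal(nrow(sample_lengths(character(0),
                                   paper_defaults()$length_model)), 0)
})

test_that("sample_covariates recovers the configured correlation structure", {
  set.seed(102)
  cm <- paper_defaults()$covariate_model
  s <- sample_covariates(10000, cm)
  expect_equal(dim(s$table), c(10000, 8))
  expect_equal(names(s$table), dga_covariate_names())
  cc <- cor(as.matrix(s$table))
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.05))   # identity by default
  # standardized deviation of sample means: SE is 1/sqrt(n) SDs
  expect_lt(max(abs(colMeans(s$table) - cm$means) / cm$sds), 0.05)
  # a configured correlation is recovered
  cm2 <- cm
  cm2$correlation[1, 6] <- cm2$correlation[6, 1] <- -0.3
  s2 <- sample_covariates(10000, cm2)
  expect_equal(cor(s2$table[[1]], s2$table[[6]]), -0.3, tolerance = 0.05)
  # degenerate n = 1 works
  expect_equal(nrow(sample_covariates(1, cm)$table), 1)
  cm_bad <- cm
  cm_bad$correlation[1, 2] <- cm_bad$correlation[2, 1] <- 0.9
  cm_bad$correlation[1, 3] <- cm_bad$correlation[3, 1] <- 0.9
  cm_bad$correlation[2, 3] <- cm_bad$correlation[3, 2] <- -0.9  # not PSD
  expect_error(sample_covariates(10, cm_bad), "positive semi-definite")
  cm_na <- cm; cm_na$correlation[1, 2] <- NA
  expect_error(sample_covariates(10, cm_na), "missing")
})

test_that("simulate_intron_pair realizes the CpG-stratified mutation process", {
  sm <- paper_defaults()$seq_model
  # zero rate: both lineages identical to the ancestor
  set.seed(103)
  z <- simulate_intron_pair("g", 5000, 0, 10, sm)
  expect_identical(z$human, z$ancestral)
  expect_identical(z$chimp, z$ancestral)
  # kappa = 10: realized divergence at the *generative* (ancestral) CpG
  # sites matches the exact two-lineage expectation: P_cpg = 2q(1-q) with
  # q = kappa*rate (two mutated CpG copies coincide on the transition),
  # P_non = 2q(1-q) + 0.56 q^2
  q <- 0.005; kap <- 10
  p_cpg <- 2 * (q * kap) * (1 - q * kap)
  p_non <- 2 * q * (1 - q) + 0.56 * q^2
  set.seed(104)
  s <- simulate_intron_pair("g", 4e5, q, kap, sm)
  h <- strsplit(s$human, "")[[1]]; c2 <- strsplit(s$chimp, "")[[1]]
  d_cpg <- mean((h != c2)[s$cpg_ancestral])
  d_non <- mean((h != c2)[!s$cpg_ancestral])
  expect_equal(d_cpg / d_non, p_cpg / p_non, tolerance = 0.08)
  # the pipeline classifier works on the mutated human sequence; CpG gain
  # and loss under mutation pull the measured class ratio towards 1
  # (the same ascertainment affects real human-referenced data)
  aln <- intron_alignment("g", s$human, s$chimp)
  d <- gene_divergence(count_divergence(aln), "g")
  expect_lt(d$d_cpg / d$d_noncpg, p_cpg / p_non)
  expect_gt(d$d_cpg / d$d_noncpg, 3)
  # kappa = 1: no elevation on the generative classes
  set.seed(105)
  s1 <- simulate_intron_pair("g", 3e5, 0.01, 1, sm)
  h1 <- strsplit(s1$human, "")[[1]]; c1 <- strsplit(s1$chimp, "")[[1]]
  expect_equal(mean((h1 != c1)[s1$cpg_ancestral]) /
               mean((h1 != c1)[!s1$cpg_ancestral]), 1, tolerance = 0.12)
  expect_error(simulate_intron_pair("g", 100, 0.05, 25, sm), "overflow")
  expect_error(simulate_intron_pair("g", 0, 0.01, 10, sm), "intron_length")
})

test_that("ancestral CpG density is thinned to the configured value", {
  set.seed(106)
  sm <- paper_defaults()$seq_model
  s <- simulate_intron_pair("g", 3e5, 0, 1, sm)
  anc <- strsplit(s$ancestral, "")[[1]]
  cpg_dinuc <- sum(anc[-length(anc)] == "C" & anc[-1] == "G") /
    (length(anc) - 1)
  expect_lt(abs(cpg_dinuc - sm$cpg_density), 0.002)
  gc <- mean(anc %in% c("G", "C"))
  # thinning replaces the G of dropped CpGs with A/T, lowering GC by about
  # the dropped dinucleotide density (~0.028 here)
  expect_lt(abs(gc - (sm$intron_gc - ((sm$intron_gc / 2)^2 -
                                      sm$cpg_density))), 0.01)
})

test_that("sample_snps realizes intensities, classes and MAF means", {
  set.seed(107)
  sm <- paper_defaults()$seq_model
  seqs <- simulate_intron_pair("g", 2e5, 0, 1, sm)
  hum <- seqs$human
  rate <- 0.004; kap <- 10; gfac <- 0.5
  snps <- sample_snps(hum, rate, kap, gfac, maf_mean = 0.11, maf_shape = 0.8)
  cls <- classify_cpg(hum)
  n_cpg <- sum(cls == 1L, na.rm = TRUE); n_non <- sum(cls == 0L, na.rm = TRUE)
  lam <- (n_cpg * kap + n_non) * 2 * rate * gfac
  expect_lt(abs(nrow(snps) - lam) / sqrt(lam), 4)   # Poisson mean recovery
  # REF matches the sequence; ALT at CpG sites is always the transition
  hchars <- strsplit(hum, "")[[1]]
  expect_equal(snps$ref, hchars[snps$offset + 1])
  at_cpg <- !is.na(cls[snps$offset + 1]) & cls[snps$offset + 1] == 1L
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  expect_true(all(snps$alt[at_cpg] == ts[snps$ref[at_cpg]]))
  expect_true(all(snps$alt != snps$ref))
  # folded MAF mean matches the configured mean (3 SE band)
  expect_lt(abs(mean(snps$maf) - 0.11),
            3 * sd(snps$maf) / sqrt(nrow(snps)))
  # af is maf or its complement
  expect_true(all(abs(pmin(snps$af, 1 - snps$af) - snps$maf) < 1e-9))
  # two class means in a 0.11 / 0.09 design recover their ratio
  snps2 <- sample_snps(hum, rate, kap, gfac, maf_mean = 0.09)
  expect_equal(mean(snps2$maf) / 0.10, 0.9, tolerance = 0.05)
  expect_equal(mean(snps$maf) / 0.10, 1.1, tolerance = 0.05)
  # guards
  expect_error(sample_snps(hum, rate, kap, 0, 0.1), "genealogy_factor")
  expect_error(sample_snps(hum, rate, kap, 1, 0.7), "maf_mean")
  # a huge intensity is capped at the available sites (one warning per class)
  expect_warning(expect_warning(
    sample_snps(substr(hum, 1, 200), 0.09, 10, 1e4, 0.1), "capping"),
    "capping")
})

test_that("generate_cohort is byte-deterministic and honours n by class", {
  cfg <- small_profile(); cfg$n_genes <- 60L
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  b1 <- generate_cohort(cfg, d1, seed = 9)
  b2 <- generate_cohort(cfg, d2, seed = 9)
  for (nm in names(b1$paths)) {
    expect_equal(unname(tools::md5sum(b1$paths[[nm]])),
                 unname(tools::md5sum(b2$paths[[nm]])), info = nm)
  }
  # a different seed changes the bundle
  d3 <- file.path(tempdir(), "det3")
  b3 <- generate_cohort(cfg, d3, seed = 10)
  expect_false(identical(unname(tools::md5sum(b1$paths$introns)),
                         unname(tools::md5sum(b3$paths$introns))))
  # truth invariants: one record per gene, strictly positive rates/factors
  expect_equal(nrow(b1$truth), 60)
  expect_true(all(b1$truth$true_rate_noncpg > 0))
  expect_true(all(b1$truth$true_genealogy_factor > 0))
  expect_true(all(table(b1$truth$gene_id) == 1))
  expect_true(all(b1$truth$chromosome %in% paste0("chr", 1:22)))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("null configuration shows no class effects in lengths", {
  cfg <- small_profile()
  cfg$length_model$class_mult_total_cds[] <- 1
  cfg$length_model$class_mult_avg_cds[] <- 1
  set.seed(108)
  classes <- sample(rep(c("none", "mendelian", "gwas"), each = 4000))
  len <- sample_lengths(classes, cfg$length_model)
  a <- one_way_anova(len$total_cds_length, classes)
  expect_gt(a$p, 1e-4)  # no fabricated signal
})

test_that("calibrate_generator converges and is a fixed point at target", {
  # a deliberately mis-set config is pulled to the targets
  cfg <- paper_defaults()
  cfg$length_model$log_length_correlation <- 0.65
  cfg$rate_model$baseline_rate <- 0.0046
  cal <- calibrate_generator(cfg, tolerance = c(0.01, 2e-4), n_sim = 2500L,
                             n_sim_lengths = 60000L, seed = 1)
  expect_lt(abs(cal$length_model$log_length_correlation -
                paper_defaults()$length_model$log_length_correlation), 0.05)
  expect_lt(abs(cal$rate_model$baseline_rate -
                paper_defaults()$rate_model$baseline_rate), 4e-4)
  # already-calibrated config: correlation knob untouched at loose tolerance
  cal2 <- calibrate_generator(paper_defaults(), tolerance = c(0.03, 1e-3),
                              n_sim = 2000L, n_sim_lengths = 50000L, seed = 2)
  expect_equal(cal2$length_model$log_length_correlation,
               paper_defaults()$length_model$log_length_correlation)
})

test_that("divergence regressed on the true rate has slope ~ 2", {
  # two lineages accumulate 2q substitutions per site; measured on the
  # generative (ancestral) non-CpG classes the regression slope is 2
  set.seed(51)
  sm <- paper_defaults()$seq_model
  rates <- rlnorm(400, log(0.0035), 0.5)
  d_gen <- vapply(seq_along(rates), function(i) {
    s <- simulate_intron_pair(paste0("g", i), 2000L, rates[i], 10, sm)
    h <- charToRaw(s$human); c2 <- charToRaw(s$chimp)
    mean((h != c2)[!s$cpg_ancestral])
  }, numeric(1))
  fit <- lm(d_gen ~ rates)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.05)

  # the pipeline's human-referenced d_noncpg inherits CpG-loss ascertainment
  # (ancestral CpG sites whose context mutated leak into the non-CpG class
  # with elevated divergence), inflating the slope by roughly 10%; the same
  # effect is present in real human-referenced alignments
  dir <- small_cohort(n = 500, seed = 51)
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  div <- divergence_table(read_intron_alignments(file.path(dir,
                                                           "introns.fasta")))
  m <- merge(truth, div, by = "gene_id")
  fit2 <- lm(d_noncpg ~ true_rate_noncpg, data = m)
  expect_gt(unname(coef(fit2)[2]), 1.9)
  expect_lt(unname(coef(fit2)[2]), 2.5)
})
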