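## Synthetic gene-cohort generator.
##
## A stated world with the observed effect sizes built in: lognormal gene
## lengths with multiplicative disease-class effects, covariate-driven
## per-gene substitution rates with hypermutable CpG sites, gamma-dispersed
## genealogy factors driving Poisson SNP counts, and truncated-Beta folded
## minor-allele frequencies with class-specific means. All randomness flows
## from one seeded Mersenne-Twister stream in a documented draw order:
## classes, chromosomes, lengths, intron counts, covariates, genealogy
## factors, then per chunk of genes (fixed chunk size 2000): intron splits,
## ancestral sequence, CpG thinning, human mutations, chimp mutations, CDS
## codons, per-gene SNPs.

.CHUNK_SIZE <- 2000L
.BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.BASE_CHARS <- c("A", "C", "G", "T")
.TS_CODE <- c(3L, 4L, 1L, 2L)                    # A<->G, C<->T
.TV_CODE <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

#' Sample per-gene lengths and transcript counts
#'
#' Total CDS and total intron lengths are correlated lognormals on the log
#' scale (`log_length_correlation`), each with per-class multiplicative
#' effects. The average CDS length is a Beta-distributed fraction of the
#' total (so a transcript can never exceed the union of exons), with the
#' per-class mean of the fraction derived from the configured average-CDS
#' multipliers. CDS lengths are rounded to multiples of 3 (minimum 9 bp)
#' and the transcript count is the smallest number of average-length
#' transcripts that can cover the total.
#'
#' @param classes character vector of disease classes, one per gene.
#' @param length_model the `length_model` component of a [cohort_config()].
#' @return `data.frame` with `total_cds_length`, `average_cds_length`,
#'   `total_intron_length`, `n_transcripts`.
#' @export
sample_lengths <- function(classes, length_model) {
  lm_ <- length_model
  n <- length(classes)
  if (n == 0L)
    return(data.frame(total_cds_length = integer(0),
                      average_cds_length = integer(0),
                      total_intron_length = integer(0),
                      n_transcripts = integer(0)))
  rho <- lm_$log_length_correlation
  z1 <- rnorm(n); z2 <- rnorm(n)
  zI <- rho * z1 + sqrt(1 - rho^2) * z2
  Tlen <- exp(lm_$total_cds_meanlog + log(lm_$class_mult_total_cds[classes]) +
              lm_$total_cds_sdlog * z1)
  Ilen <- exp(lm_$intron_meanlog + log(lm_$class_mult_intron[classes]) +
              lm_$intron_sdlog * zI)
  mu <- lm_$avg_ratio_base * lm_$class_mult_avg_cds[classes] /
    lm_$class_mult_total_cds[classes]
  nu <- lm_$avg_ratio_precision
  B <- rbeta(n, mu * nu, (1 - mu) * nu)
  B <- pmin(pmax(B, 1e-6), 1)
  T3 <- 3L * pmax(3L, as.integer(round(Tlen / 3)))
  A3 <- pmin(3L * pmax(1L, as.integer(round(B * T3 / 3))), T3)
  data.frame(total_cds_length = T3,
             average_cds_length = A3,
             total_intron_length = as.integer(pmax(round(Ilen), 100)),
             n_transcripts = as.integer(ceiling(T3 / A3)),
             row.names = NULL)
}

#' Sample the 8-covariate table
#'
#' Multivariate normal with the configured means, SDs and correlation
#' matrix (Cholesky of the correlation; a non-PSD matrix is a validation
#' error). Column names follow [dga_covariate_names()].
#'
#' @param n number of genes.
#' @param covariate_model the `covariate_model` component of a config.
#' @return list with `table` (data.frame, n x 8) and `z` (the standardized
#'   draws actually used, needed by the rate model).
#' @export
sample_covariates <- function(n, covariate_model) {
  cm <- covariate_model
  R <- cm$correlation
  if (anyNA(R)) stop("correlation matrix contains missing values")
  if (!isTRUE(all.equal(R, t(R)))) stop("correlation matrix must be symmetric")
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is not positive semi-definite"))
  z <- matrix(rnorm(n * 8L), ncol = 8L) %*% ch
  x <- sweep(sweep(z, 2L, cm$sds, `*`), 2L, cm$means, `+`)
  colnames(x) <- cm$names
  tab <- as.data.frame(x, check.names = FALSE)
  list(table = tab, z = z)
}

#' Simulate a pairwise intron alignment for one gene
#'
#' An ancestral sequence with the configured GC fraction and CpG
#' dinucleotide density is mutated independently along the human and chimp
#' lineages. Per-site substitution probability is `rate_noncpg` at non-CpG
#' sites and `kappa * rate_noncpg` at CpG sites (CpG status is decided once
#' on the ancestral sequence); a substitution is the transition with
#' probability 1 at CpG sites and 0.6 elsewhere, transversions
#' equiprobable. No indels are simulated, so the two sequences come back
#' aligned position-by-position.
#'
#' @param gene_id identifier (carried into the result).
#' @param intron_length ungapped length (>= 1).
#' @param rate_noncpg per-lineage non-CpG substitution probability, in
#'   (0, 0.1) (0 allowed for the degenerate no-mutation case).
#' @param kappa CpG rate multiplier (>= 1); `rate_noncpg * kappa` must stay
#'   below 1.
#' @param seq_model the `seq_model` component of a config.
#' @return list with `gene_id`, `human`, `chimp`, `ancestral` (strings) and
#'   `cpg_ancestral` (logical per site).
#' @export
simulate_intron_pair <- function(gene_id, intron_length, rate_noncpg, kappa,
                                 seq_model = paper_defaults()$seq_model) {
  if (intron_length < 1) stop("intron_length must be >= 1")
  if (rate_noncpg < 0 || rate_noncpg >= 0.1)
    stop("rate_noncpg must be in [0, 0.1)")
  if (kappa < 1) stop("kappa must be >= 1")
  if (rate_noncpg * kappa >= 1)
    stop("rate_noncpg * kappa >= 1: per-site substitution probability overflow")
  sim <- .sim_sequences(as.integer(intron_length), rate_noncpg, kappa, seq_model)
  list(gene_id = gene_id,
       human = sim$human_str[1], chimp = sim$chimp_str[1],
       ancestral = sim$anc_str[1],
       cpg_ancestral = sim$cpg_anc)
}

## Core vectorized simulator over a chunk of genes.
## L: integer intron lengths; q: per-gene non-CpG substitution probability.
## Returns integer code vectors plus per-gene strings.
.sim_sequences <- function(L, q, kappa, seq_model, keep_codes = FALSE) {
  tot <- sum(L)
  ng <- length(L)
  gidx <- rep.int(seq_len(ng), L)
  gc <- seq_model$intron_gc
  anc <- sample.int(4L, tot, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  # thin CpG dinucleotides down to the configured density
  p_iid <- (gc / 2)^2
  keep_p <- min(1, seq_model$cpg_density / p_iid)
  if (keep_p < 1 && tot > 1L) {
    nxt <- c(anc[-1L], 0L)
    same <- c(gidx[-1L] == gidx[-tot], FALSE)
    cpg_c <- which(anc == 2L & nxt == 3L & same)
    drop <- cpg_c[runif(length(cpg_c)) > keep_p]
    if (length(drop))
      anc[drop + 1L] <- ifelse(runif(length(drop)) < 0.5, 1L, 4L)
  }
  # CpG status on the ancestral sequence (gene-boundary aware)
  if (tot > 1L) {
    nxt <- c(anc[-1L], 0L)
    same_n <- c(gidx[-1L] == gidx[-tot], FALSE)
    prv <- c(0L, anc[-tot])
    same_p <- c(FALSE, same_n[-tot])
    iscpg <- (anc == 2L & nxt == 3L & same_n) |
             (anc == 3L & prv == 2L & same_p)
  } else iscpg <- FALSE
  qq <- q[gidx] * (1 + (kappa - 1) * iscpg)
  if (any(qq >= 1)) stop("per-site substitution probability >= 1")
  mutate <- function() {
    s <- anc
    m <- which(runif(tot) < qq)
    if (length(m)) {
      ists <- iscpg[m] | (runif(length(m)) < 0.6)
      s[m[ists]] <- .TS_CODE[anc[m[ists]]]
      tvm <- m[!ists]
      if (length(tvm)) {
        pick <- 1L + (runif(length(tvm)) < 0.5)
        s[tvm] <- .TV_CODE[cbind(anc[tvm], pick)]
      }
    }
    s
  }
  hum <- mutate()
  chp <- mutate()
  ends <- cumsum(L); starts <- ends - L + 1L
  to_str <- function(v) {
    big <- rawToChar(.dga$base_raw[v])
    substring(big, starts, ends)
  }
  out <- list(human_str = to_str(hum), chimp_str = to_str(chp),
              anc_str = to_str(anc), cpg_anc = iscpg, gidx = gidx)
  if (keep_codes) { out$human <- hum; out$chimp <- chp }
  out
}

## Human-sequence CpG classification over a chunk (integer codes, no N/gaps):
## 1 = CpG, 0 = non-CpG, NA = unclassifiable (gene-terminal C or G whose
## deciding neighbour is off the end). Matches classify_cpg().
.classify_chunk <- function(hum, gidx) {
  tot <- length(hum)
  if (tot == 0L) return(integer(0))
  isC <- hum == 2L; isG <- hum == 3L
  nxtG <- c(isG[-1L], FALSE)
  same_n <- if (tot > 1L) c(gidx[-1L] == gidx[-tot], FALSE) else FALSE
  prvC <- c(FALSE, isC[-tot])
  same_p <- c(FALSE, same_n[-tot])
  cls <- integer(tot)
  cls[(isC & nxtG & same_n) | (isG & prvC & same_p)] <- 1L
  cls[isC & !same_n] <- NA_integer_   # C at a gene end: no deciding neighbour
  cls[isG & !same_p] <- NA_integer_   # G at a gene start: no deciding neighbour
  cls
}

#' Sample intronic SNPs for one gene
#'
#' SNP counts per CpG class are Poisson with mean
#' `sites * 2 * rate * kappa_class * genealogy_factor`, where
#' `genealogy_factor` already carries the diversity scaling and per-class
#' SNP-density multiplier (see the vignette); `2 * rate` is the
#' divergence-scale substitution rate of the site class. Positions are
#' uniform within class without replacement; each SNP gets a folded minor
#' allele frequency from a truncated Beta on (0, 0.5] with the configured
#' class mean, and its ALT allele is the transition with probability 1 at
#' CpG sites and 0.6 elsewhere.
#'
#' @param human_seq the gene's (ungapped) human intron sequence.
#' @param rate_noncpg per-lineage non-CpG substitution probability.
#' @param kappa CpG rate multiplier.
#' @param genealogy_factor positive per-gene genealogy scaling.
#' @param maf_mean mean folded MAF in (0, 0.5).
#' @param maf_shape Beta shape parameter `a`.
#' @return `data.frame` with `offset` (0-based), `ref`, `alt`, `maf`, `af`.
#' @export
sample_snps <- function(human_seq, rate_noncpg, kappa, genealogy_factor,
                        maf_mean, maf_shape = 0.8) {
  if (genealogy_factor <= 0) stop("genealogy_factor must be > 0")
  if (maf_mean <= 0 || maf_mean >= 0.5) stop("maf_mean must be in (0, 0.5)")
  hum <- .BASE_CODES[strsplit(toupper(human_seq), "")[[1]]]
  if (anyNA(hum)) stop("human_seq must be over ACGT")
  cls <- .classify_chunk(unname(hum), rep(1L, length(hum)))
  .sample_snps_gene(unname(hum), cls, rate_noncpg, kappa, genealogy_factor,
                    maf_mean, maf_shape)
}

## Core single-gene SNP sampler on integer codes + class vector.
.sample_snps_gene <- function(hum, cls, rate, kappa, gfac, maf_mean,
                              maf_shape) {
  sites_cpg <- which(!is.na(cls) & cls == 1L)
  sites_non <- which(!is.na(cls) & cls == 0L)
  lam_cpg <- length(sites_cpg) * 2 * rate * kappa * gfac
  lam_non <- length(sites_non) * 2 * rate * gfac
  n_cpg <- rpois(1L, lam_cpg)
  n_non <- rpois(1L, lam_non)
  if (n_cpg > length(sites_cpg)) {
    warning("requested ", n_cpg, " CpG SNPs but only ", length(sites_cpg),
            " CpG sites; capping")
    n_cpg <- length(sites_cpg)
  }
  if (n_non > length(sites_non)) {
    warning("requested ", n_non, " non-CpG SNPs but only ", length(sites_non),
            " sites; capping")
    n_non <- length(sites_non)
  }
  pos <- c(if (n_cpg) sites_cpg[sample.int(length(sites_cpg), n_cpg)],
           if (n_non) sites_non[sample.int(length(sites_non), n_non)])
  n <- length(pos)
  if (n == 0L)
    return(data.frame(offset = integer(0), ref = character(0),
                      alt = character(0), maf = numeric(0), af = numeric(0)))
  is_cpg <- c(rep(TRUE, n_cpg), rep(FALSE, n_non))
  refc <- hum[pos]
  ists <- is_cpg | (runif(n) < 0.6)
  altc <- integer(n)
  altc[ists] <- .TS_CODE[refc[ists]]
  if (any(!ists)) {
    pick <- 1L + (runif(sum(!ists)) < 0.5)
    altc[!ists] <- .TV_CODE[cbind(refc[!ists], pick)]
  }
  b <- maf_shape * (0.5 - maf_mean) / maf_mean
  maf <- 0.5 * rbeta(n, maf_shape, b)
  maf <- pmin(pmax(maf, 1e-6), 0.5)
  af <- ifelse(runif(n) < 0.5, maf, 1 - maf)
  o <- order(pos)
  data.frame(offset = pos[o] - 1L, ref = .BASE_CHARS[refc[o]],
             alt = .BASE_CHARS[altc[o]], maf = maf[o], af = af[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

## GC-tilted sense-codon sampling probabilities: p(codon) ~ w^gc(codon),
## with w solved so the expected GC fraction matches the target.
.sense_codon_probs <- function(cds_gc) {
  .init_code_tables()
  cods <- names(.dga$code)[.dga$code != "*"]
  gcn <- vapply(strsplit(cods, ""), function(b) sum(b %in% c("G", "C")),
                numeric(1))
  f <- function(logw) {
    p <- exp(gcn * logw); p <- p / sum(p)
    sum(p * gcn) / 3 - cds_gc
  }
  logw <- stats::uniroot(f, c(-5, 5))$root
  p <- exp(gcn * logw)
  list(codons = cods, probs = p / sum(p))
}

#' Generate a complete synthetic cohort bundle
#'
#' Writes `genes.gff3`, `introns.fasta` (two records per gene,
#' `geneID|human` and `geneID|chimp`), `cds.fasta` (one record per
#' transcript), `snps.vcf` (VCFv4.2 with INFO/AF), `covariates.tsv`,
#' `classes.tsv` and `truth.tsv` into `out_dir`. All genes are autosomal by
#' construction. The same config and seed yield byte-identical files.
#'
#' @param config a [cohort_config()] object.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @param quiet suppress the per-stage progress messages.
#' @return invisibly, a list with the file `paths` and the `truth` table.
#' @export
generate_cohort <- function(config = paper_defaults(), out_dir,
                            seed = NULL, quiet = TRUE) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ",
                                         out_dir)
  .init_code_tables()
  if (is.null(.dga$base_raw)) .dga$base_raw <- charToRaw("ACGT")
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_genes)
  say <- function(...) if (!quiet) message("synth: ", ...)

  ## 1. classes (largest-remainder rounding, then a random permutation)
  cf <- config$class_fractions[.CLASS_LEVELS]
  counts <- floor(cf * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(cf * n - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  classes <- sample(rep(.CLASS_LEVELS, counts))
  gene_id <- sprintf("g%06d", seq_len(n))

  ## 2. chromosomes
  chrom <- paste0("chr", sample.int(22L, n, replace = TRUE))

  ## 3. lengths, 4. intron counts, 5. covariates, 6. genealogy factors
  len <- sample_lengths(classes, config$length_model)
  k_introns <- 1L + rpois(n, max(0, config$length_model$introns_per_gene - 1))
  k_introns <- pmin(k_introns, pmax(1L, len$total_cds_length %/% 3L - 1L))
  # floor of 30 bp per intron piece; realized totals go into the truth table
  len$total_intron_length <- pmax(len$total_intron_length, 30L * k_introns)
  cov <- sample_covariates(n, config$covariate_model)
  rm_ <- config$rate_model
  rate <- rm_$baseline_rate *
    exp(as.numeric(cov$z %*% rm_$coefficients))
  q_gene <- rate * rm_$class_mult_divergence[classes]   # per-lineage, non-CpG
  if (any(q_gene * rm_$cpg_multiplier >= 1))
    stop("rate model implies per-site substitution probability >= 1")
  dm <- config$diversity_model
  phi <- dm$genealogy_dispersion
  G <- if (phi > 0) rgamma(n, shape = 1 / phi, rate = 1 / phi) else rep(1, n)
  G <- pmax(G, 1e-8)
  # genealogy scaling entering the Poisson SNP intensity: the intensity uses
  # the class-free base rate, so the realized SNP-density ratio between
  # classes equals class_mult_snp_density exactly; the expected pi/d ratio
  # (true_genealogy_factor) additionally divides by the divergence
  # multiplier and is only checked directionally (see vignette)
  gfac <- dm$pi_over_div * dm$class_mult_snp_density[classes] * G

  ## gene placement: genes stacked per chromosome with fixed 10 kb gaps
  span <- len$total_cds_length + len$total_intron_length
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1L, head(span[i] + 10000L, -1L)))
  }

  ## per-chunk simulation
  codon_model <- .sense_codon_probs(config$seq_model$cds_gc)
  paths <- list(
    gff3 = file.path(out_dir, "genes.gff3"),
    introns = file.path(out_dir, "introns.fasta"),
    cds = file.path(out_dir, "cds.fasta"),
    vcf = file.path(out_dir, "snps.vcf"),
    covariates = file.path(out_dir, "covariates.tsv"),
    classes = file.path(out_dir, "classes.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  gff_con <- file(paths$gff3, "w")
  writeLines("##gff-version 3", gff_con)
  fasta_con <- file(paths$introns, "w")
  cds_con <- file(paths$cds, "w")
  vcf_rows <- vector("list", ceiling(n / .CHUNK_SIZE))
  say(n, " genes in ", length(vcf_rows), " chunks")

  chunk_no <- 0L
  for (cs in seq(1L, n, by = .CHUNK_SIZE)) {
    chunk_no <- chunk_no + 1L
    ce <- min(cs + .CHUNK_SIZE - 1L, n)
    idx <- cs:ce
    ni <- k_introns[idx]
    Itot <- len$total_intron_length[idx]

    ## (a) intron piece lengths: exponential spacings, floor 30 bp
    pieces <- vector("list", length(idx))
    e_all <- rexp(sum(ni))
    off <- 0L
    for (j in seq_along(idx)) {
      k <- ni[j]
      e <- e_all[off + seq_len(k)]; off <- off + k
      avail <- Itot[j] - 30L * k
      extra <- floor(avail * e / sum(e))
      extra[1L] <- extra[1L] + (avail - sum(extra))
      pieces[[j]] <- 30L + extra
    }
    L <- vapply(pieces, sum, numeric(1))

    ## (b-e) sequences
    sim <- .sim_sequences(as.integer(L), q_gene[idx],
                          rm_$cpg_multiplier, config$seq_model,
                          keep_codes = TRUE)
    writeLines(paste0(">", gene_id[idx], "|human\n", sim$human_str,
                      "\n>", gene_id[idx], "|chimp\n", sim$chimp_str),
               fasta_con)

    ## (f) CDS union sequences (sense codons only, GC-tilted)
    T3 <- len$total_cds_length[idx]
    n_cod <- T3 %/% 3L
    cod_idx <- sample.int(length(codon_model$codons), sum(n_cod),
                          replace = TRUE, prob = codon_model$probs)
    big_cds <- paste(codon_model$codons[cod_idx], collapse = "")
    cends <- cumsum(n_cod) * 3L
    cstarts <- cends - T3 + 1L
    cds_union <- substring(big_cds, cstarts, cends)

    ## gene structures + GFF3 + transcript CDS records
    gff_lines <- vector("list", length(idx))
    cds_lines <- vector("list", length(idx))
    intron_iv <- vector("list", length(idx))
    cls_chunk <- .classify_chunk(sim$human, sim$gidx)
    gends <- cumsum(L); gstarts <- gends - L + 1L

    ## (g) SNPs (per gene; single RNG stream, gene order)
    snp_chunk <- vector("list", length(idx))

    for (j in seq_along(idx)) {
      g <- idx[j]
      st <- .gene_structure(gene_id[g], chrom[g], start[g], T3[j],
                            len$average_cds_length[g], pieces[[j]])
      gff_lines[[j]] <- st$gff
      intron_iv[[j]] <- st$introns
      cds_lines[[j]] <- paste0(">", st$tx_ids, "\n",
                               substring(cds_union[j], st$tx_from, st$tx_to))
      cls_g <- cls_chunk[gstarts[j]:gends[j]]
      hum_g <- sim$human[gstarts[j]:gends[j]]
      snps <- .sample_snps_gene(hum_g, cls_g, rate[g],
                                rm_$cpg_multiplier, gfac[g],
                                dm$maf_means[[classes[g]]], dm$maf_shape)
      if (nrow(snps)) {
        # map intron-sequence offsets to genomic positions
        cum <- cumsum(c(0L, head(pieces[[j]], -1L)))
        piece_i <- findInterval(snps$offset, cum)
        gpos <- st$introns[piece_i, 1L] + (snps$offset - cum[piece_i])
        snp_chunk[[j]] <- data.table::data.table(
          chrom = chrom[g], pos = gpos, ref = snps$ref, alt = snps$alt,
          af = snps$af, gene = gene_id[g])
      }
    }
    writeLines(unlist(gff_lines), gff_con)
    writeLines(unlist(cds_lines), cds_con)
    vcf_rows[[chunk_no]] <- data.table::rbindlist(snp_chunk)
    say("chunk ", chunk_no, " done (genes ", cs, "-", ce, ")")
  }
  close(gff_con); close(fasta_con); close(cds_con)

  ## VCF (sorted by chromosome, position)
  snps_all <- data.table::rbindlist(vcf_rows)
  if (nrow(snps_all)) {
    chrom_n <- as.integer(sub("chr", "", snps_all$chrom))
    snps_all <- snps_all[order(chrom_n, snps_all$pos)]
  }
  .write_vcf(snps_all, paths$vcf)

  ## tables
  cov_tab <- cbind(data.frame(gene_id = gene_id, stringsAsFactors = FALSE),
                   cov$table)
  data.table::fwrite(cov_tab, paths$covariates, sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(gene_id = gene_id, class = classes),
                     paths$classes, sep = "\t", quote = FALSE)
  truth <- data.frame(
    gene_id = gene_id, disease_class = classes, chromosome = chrom,
    total_cds_length = len$total_cds_length,
    average_cds_length = len$average_cds_length,
    total_intron_length = len$total_intron_length,
    n_transcripts = len$n_transcripts, n_introns = k_introns,
    true_rate_noncpg = q_gene,
    true_genealogy_factor = gfac / rm_$class_mult_divergence[classes],
    stringsAsFactors = FALSE)
  data.table::fwrite(truth, paths$truth, sep = "\t", quote = FALSE)
  invisible(list(paths = paths, truth = truth, config = config))
}

## Build one gene's exon/intron structure and GFF3 lines.
## Union CDS [0, T3) is cut at evenly spaced points into exons with the
## intron pieces inserted between them; transcripts are A3-length windows
## of the union at multiple-of-3 offsets, together covering all of it.
.gene_structure <- function(gid, chrom, gstart, T3, A3, pieces) {
  k <- length(pieces)
  cuts <- unique(pmin(pmax(round(T3 * seq_len(k) / (k + 1)), 1L), T3 - 1L))
  k <- length(cuts)
  pieces <- pieces[seq_len(k)]
  ex_from <- c(0L, cuts)              # union coords, half-open
  ex_to <- c(cuts, T3)
  # genomic starts of each exon: cumulative exon+intron lengths
  ex_len <- ex_to - ex_from
  gpos <- gstart + cumsum(c(0L, head(ex_len, -1L) + pieces))
  ex_g_from <- gpos                   # 1-based genomic start of each exon
  ex_g_to <- gpos + ex_len - 1L
  introns <- cbind(ex_g_to[-length(ex_g_to)] + 1L,
                   ex_g_from[-1L] - 1L)  # 1-based closed genomic intervals
  gene_end <- ex_g_to[length(ex_g_to)]
  n_tx <- as.integer(ceiling(T3 / A3))
  w <- if (n_tx == 1L) 0L else
    as.integer(round((T3 - A3) * (seq_len(n_tx) - 1L) / (n_tx - 1L) / 3)) * 3L
  tx_ids <- sprintf("%s.t%d", gid, seq_len(n_tx))
  lines <- sprintf("%s\tdga\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, gstart,
                   gene_end, gid)
  for (t in seq_len(n_tx)) {
    wf <- w[t]; wt <- w[t] + A3      # union coords, half-open
    ov_from <- pmax(ex_from, wf)
    ov_to <- pmin(ex_to, wt)
    keep <- ov_from < ov_to
    cf <- ov_from[keep]; ct <- ov_to[keep]
    g_from <- ex_g_from[keep] + (cf - ex_from[keep])
    g_to <- g_from + (ct - cf) - 1L
    phase <- (3L - (cumsum(c(0L, head(ct - cf, -1L))) %% 3L)) %% 3L
    lines <- c(lines,
      sprintf("%s\tdga\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s", chrom,
              g_from[1L], g_to[length(g_to)], tx_ids[t], gid),
      sprintf("%s\tdga\tCDS\t%d\t%d\t.\t+\t%d\tID=%s.cds;Parent=%s", chrom,
              g_from, g_to, phase, tx_ids[t], tx_ids[t]))
  }
  list(gff = lines, introns = introns, tx_ids = tx_ids,
       tx_from = w + 1L, tx_to = w + A3)
}

.write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dga-synthetic-cohort",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Source gene\">",
           paste0("##contig=<ID=chr", 1:22, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (NROW(snps) && ncol(snps)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f;GENE=%s",
                                  snps$chrom, snps$pos, snps$ref, snps$alt,
                                  snps$af, snps$gene) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
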