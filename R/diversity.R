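## Intronic SNP density, genealogy length and minor allele frequency.
##
## SNP density divided by divergence cancels the local mutation rate and
## leaves a quantity proportional to the average coalescent genealogy
## length at the locus. Densities are computed on the same masked,
## classifiable-site basis as divergence so the two denominators match.

#' Fold allele frequencies to minor allele frequencies
#'
#' `f` and `1 - f` map to the same folded value `min(f, 1 - f)`; exactly
#' 0.5 maps to 0.5. Folding is idempotent.
#'
#' @param f numeric vector of allele frequencies in `[0, 1]`.
#' @return folded frequencies in `[0, 0.5]`.
#' @export
fold_maf <- function(f) {
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pmin(f, 1 - f)
}

#' Mean folded minor allele frequency of a gene's SNPs
#'
#' Monomorphic records (`f` of exactly 0 or 1) are dropped, not errors.
#'
#' @param af allele frequencies in `[0, 1]` (ALT frequency; orientation is
#'   irrelevant after folding).
#' @return mean folded MAF, or `NA` if no polymorphic records remain.
#' @export
mean_maf <- function(af) {
  if (length(af) == 0L) return(NA_real_)
  if (anyNA(af)) stop("missing allele frequency")
  af <- af[af > 0 & af < 1]
  if (length(af) == 0L) return(NA_real_)
  mean(fold_maf(af))
}

#' Genealogy-length statistic
#'
#' The per-gene intronic SNP density divided by the per-gene intron
#' divergence; proportional to the average genealogy length with the local
#' mutation rate cancelled. Missing (never infinite) when divergence is
#' missing or zero.
#'
#' @param pi_all SNPs per site.
#' @param d_all divergence per site.
#' @return dimensionless ratio (vectorized).
#' @export
genealogy_length <- function(pi_all, d_all) {
  out <- ifelse(!is.na(d_all) & d_all > 0, pi_all / d_all, NA_real_)
  out[is.na(pi_all)] <- NA_real_
  out
}

#' Per-gene intronic SNP density by site class
#'
#' SNP positions are given as 0-based offsets into the *ungapped human*
#' intron sequence of the alignment. The density denominator is the number
#' of classifiable intronic sites, counted on the same masked basis as
#' divergence (unmasked, ungapped in both species, non-N, CpG-classifiable);
#' a SNP's class is the CpG class of its reference-context site. SNPs at
#' unclassifiable sites are excluded from the class densities (and tallied).
#'
#' @param alignment a [intron_alignment()] object for the gene.
#' @param snp_offsets integer vector of 0-based offsets into the ungapped
#'   human sequence.
#' @param snp_ref reference alleles; checked against the human sequence
#'   (error naming the position on disagreement).
#' @param denominator `"classifiable"` (default, matches the divergence
#'   denominator) or `"raw"` (ungapped human intron length).
#' @return list with `pi_all`, `pi_cpg`, `pi_noncpg`, `n_snps`,
#'   `n_unclassifiable_snps`, `sites_all`, `sites_cpg`, `sites_noncpg`.
#' @export
intronic_snp_density <- function(alignment, snp_offsets, snp_ref = NULL,
                                 denominator = c("classifiable", "raw")) {
  stopifnot(inherits(alignment, "dga_alignment"))
  denominator <- match.arg(denominator)
  h <- charToRaw(alignment$human)
  gap <- charToRaw("-"); nn <- charToRaw("N")
  keep <- h != gap
  cls <- classify_cpg(alignment$human)
  c2 <- charToRaw(alignment$chimp)
  usable <- !alignment$exon_mask & keep & c2 != gap & h != nn & c2 != nn &
    !is.na(cls)
  n_cpg <- sum(usable & cls == 1L, na.rm = TRUE)
  n_non <- sum(usable & cls == 0L, na.rm = TRUE)
  ulen <- sum(keep)
  # map ungapped offsets to alignment columns
  col_of <- which(keep)
  if (length(snp_offsets)) {
    if (any(snp_offsets < 0L | snp_offsets >= ulen))
      stop("SNP offset out of range for gene ", alignment$gene_id)
    cols <- col_of[snp_offsets + 1L]
    if (!is.null(snp_ref)) {
      refs <- rawToChar(h[cols], multiple = TRUE)
      bad <- which(refs != toupper(snp_ref))
      if (length(bad))
        stop("SNP reference allele disagrees with intron sequence for gene ",
             alignment$gene_id, " at offset ", snp_offsets[bad[1]],
             " (sequence ", refs[bad[1]], ", VCF ", snp_ref[bad[1]], ")")
    }
    snp_cls <- cls[cols]
  } else snp_cls <- integer(0)
  n_snps <- length(snp_offsets)
  n_uncl <- sum(is.na(snp_cls))
  den_all <- if (denominator == "raw") ulen else n_cpg + n_non
  list(
    pi_all = if (den_all > 0) n_snps / den_all else NA_real_,
    pi_cpg = if (n_cpg > 0) sum(snp_cls == 1L, na.rm = TRUE) / n_cpg else NA_real_,
    pi_noncpg = if (n_non > 0) sum(snp_cls == 0L, na.rm = TRUE) / n_non else NA_real_,
    n_snps = n_snps,
    n_unclassifiable_snps = n_uncl,
    sites_all = den_all, sites_cpg = n_cpg, sites_noncpg = n_non)
}

#' Per-gene diversity table
#'
#' Maps SNPs to genes, computes class-stratified intronic SNP densities,
#' the genealogy-length statistic (using a supplied divergence table) and
#' the mean folded MAF.
#'
#' @param alignments list of [intron_alignment()] objects, one per gene
#'   (the human record is the reference intron sequence).
#' @param snps `data.frame` with columns `gene_id`, `offset` (0-based into
#'   the ungapped human intron sequence), `ref`, `af` (ALT allele
#'   frequency). See [read_snps()] for the VCF adapter.
#' @param divergence optional per-gene [divergence_table()]; required for
#'   the genealogy statistic.
#' @param denominator see [intronic_snp_density()].
#' @return `data.frame` with one row per alignment gene: `gene_id`,
#'   `pi_all`, `pi_cpg`, `pi_noncpg`, `genealogy_length`, `mean_maf`,
#'   `n_snps`.
#' @export
diversity_table <- function(alignments, snps, divergence = NULL,
                            denominator = "classifiable") {
  ids <- vapply(alignments, `[[`, character(1), "gene_id")
  snp_by_gene <- if (nrow(snps))
    split(snps, factor(snps$gene_id, levels = ids)) else NULL
  empty <- data.frame(offset = integer(0), ref = character(0),
                      af = numeric(0))
  rows <- lapply(seq_along(alignments), function(i) {
    s <- if (is.null(snp_by_gene)) NULL else snp_by_gene[[ids[i]]]
    if (is.null(s)) s <- empty
    dens <- intronic_snp_density(alignments[[i]], s$offset, s$ref,
                                 denominator = denominator)
    c(dens$pi_all, dens$pi_cpg, dens$pi_noncpg, mean_maf(s$af), dens$n_snps,
      dens$sites_cpg, dens$sites_noncpg)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(gene_id = ids, pi_all = m[, 1], pi_cpg = m[, 2],
                    pi_noncpg = m[, 3], mean_maf = m[, 4], n_snps = m[, 5],
                    sites_cpg = m[, 6], sites_noncpg = m[, 7],
                    stringsAsFactors = FALSE)
  if (!is.null(divergence)) {
    d_all <- divergence$d_all[match(out$gene_id, divergence$gene_id)]
    out$genealogy_length <- genealogy_length(out$pi_all, d_all)
  } else out$genealogy_length <- NA_real_
  out
}
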