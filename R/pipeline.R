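## Pipeline orchestration: divergence -> opportunity -> diversity -> join
## -> stats, with the sex-chromosome filter applied before any statistic
## (the Y chromosome mutates faster and the X slower than autosomes, so
## sex-linked genes would bias every rate comparison).

#' Derived per-gene quantities from a gene model
#'
#' Total CDS length is the width of the union of all transcripts' CDS
#' pieces ("constitutive and alternatively spliced exons"); average CDS
#' length is the mean per-transcript CDS length; intron intervals are the
#' gaps between consecutive union exons; total intron length is their
#' summed width.
#'
#' @param gm a [gene_model()].
#' @return list with `lengths` (data.frame: gene_id, chromosome,
#'   disease-class-free length columns, n_transcripts) and `introns`
#'   (data.frame: gene_id, chromosome, start, end; 0-based half-open).
#' @export
gene_model_metrics <- function(gm) {
  stopifnot(inherits(gm, "dga_genemodel"))
  cds <- gm$cds
  gid_of_tx <- setNames(gm$transcripts$gene_id, gm$transcripts$transcript_id)
  cds_gene <- gid_of_tx[cds$transcript_id]
  if (anyNA(cds_gene)) stop("CDS pieces with unknown transcript parent")
  gr <- GRanges(cds$chromosome, IRanges(cds$start + 1L, cds$end))
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, factor(cds_gene,
                                          levels = gm$genes$gene_id)))
  total_cds <- sum(GenomicRanges::width(grl))
  # per-transcript CDS lengths
  tx_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  avg_cds <- tapply(as.numeric(tx_len[gm$transcripts$transcript_id]),
                    gm$transcripts$gene_id, mean)
  n_tx <- tapply(gm$transcripts$transcript_id, gm$transcripts$gene_id, length)
  rng <- unlist(range(grl))
  intr <- GenomicRanges::psetdiff(rng, grl)
  intrl <- unlist(intr)
  gids <- gm$genes$gene_id
  introns <- data.frame(
    gene_id = rep(gids, S4Vectors::elementNROWS(intr)),
    chromosome = as.character(seqnames(intrl)),
    start = start(intrl) - 1L, end = end(intrl),
    stringsAsFactors = FALSE)
  lengths <- data.frame(
    gene_id = gids,
    chromosome = gm$genes$chromosome,
    total_cds_length = as.numeric(total_cds[gids]),
    average_cds_length = as.numeric(avg_cds[gids]),
    total_intron_length = as.numeric(tapply(introns$end - introns$start,
                                            factor(introns$gene_id,
                                                   levels = gids), sum)),
    n_transcripts = as.integer(n_tx[gids]),
    stringsAsFactors = FALSE)
  lengths$total_intron_length[is.na(lengths$total_intron_length)] <- 0
  list(lengths = lengths, introns = introns)
}

#' Map VCF SNPs to genes and intron-sequence offsets
#'
#' Intersects SNP positions with the genes' intron intervals and converts
#' each genomic position to a 0-based offset into the concatenated intron
#' sequence of its gene (the coordinate system of the alignment FASTA).
#' SNPs outside any intron are tallied, not errors.
#'
#' @param snps `data.frame` from [read_snps()].
#' @param introns intron interval table from [gene_model_metrics()].
#' @return list with `snps` (the input rows that landed in introns plus
#'   `gene_id` and `offset`) and `n_outside`.
#' @export
map_snps_to_introns <- function(snps, introns) {
  if (nrow(snps) == 0L)
    return(list(snps = cbind(snps, gene_id = character(0),
                             offset = integer(0)), n_outside = 0L))
  io <- introns[order(introns$gene_id, introns$start), , drop = FALSE]
  w <- io$end - io$start
  cum <- unlist(lapply(split(w, factor(io$gene_id, levels = unique(io$gene_id))),
                       function(v) cumsum(c(0L, head(v, -1L)))),
                use.names = FALSE)
  igr <- GRanges(io$chromosome, IRanges(io$start + 1L, io$end))
  sgr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos))
  hits <- findOverlaps(sgr, igr)
  qi <- queryHits(hits); si <- subjectHits(hits)
  out <- snps[qi, , drop = FALSE]
  out$gene_id <- io$gene_id[si]
  out$offset <- as.integer(snps$pos[qi] - 1L - io$start[si] + cum[si])
  rownames(out) <- NULL
  list(snps = out, n_outside = nrow(snps) - length(unique(qi)))
}

#' Run the full analysis pipeline on a cohort bundle
#'
#' Stages run in dependency order: read gene models, alignments, CDS and
#' SNPs; compute divergence, opportunity and diversity tables; join them
#' (inner, on `gene_id`) with the covariate and class tables; drop
#' sex-chromosome genes; run the statistical report. Per-stage row counts
#' and exclusion tallies are collected in `log` and emitted via `message()`.
#'
#' @param dir bundle directory as written by [generate_cohort()]; individual
#'   paths can be overridden via `paths`.
#' @param out_dir optional output directory for `gene_table.tsv`,
#'   `report.tsv`, `report.json`, `report.txt` and `manifest.json`.
#' @param paths named list overriding any of `gff3`, `introns`, `cds`,
#'   `vcf`, `covariates`, `classes`.
#' @param exclude_chromosomes chromosomes removed before any statistic.
#' @param denominator SNP-density denominator, see [intronic_snp_density()].
#' @param log_log,pooled_t forwarded to [run_report()].
#' @param quiet suppress progress messages.
#' @return list with `gene_table`, `report`, `log`.
#' @export
run_pipeline <- function(dir = NULL, out_dir = NULL, paths = list(),
                         exclude_chromosomes = c("chrX", "chrY", "X", "Y"),
                         denominator = "classifiable",
                         log_log = FALSE, pooled_t = FALSE, quiet = FALSE) {
  def <- function(nm, fname)
    if (!is.null(paths[[nm]])) paths[[nm]] else file.path(dir, fname)
  p <- list(gff3 = def("gff3", "genes.gff3"),
            introns = def("introns", "introns.fasta"),
            cds = def("cds", "cds.fasta"),
            vcf = def("vcf", "snps.vcf"),
            covariates = def("covariates", "covariates.tsv"),
            classes = def("classes", "classes.tsv"))
  for (nm in names(p)) if (!file.exists(p[[nm]]))
    stop("input for stage '", nm, "' does not exist: ", p[[nm]])
  logl <- list()
  say <- function(...) { if (!quiet) message("pipeline: ", ...) }

  gm <- read_gff3_genes(p$gff3)
  met <- gene_model_metrics(gm)
  logl$n_genes_gff3 <- nrow(met$lengths)
  say("gene models: ", logl$n_genes_gff3, " genes")

  aln <- read_intron_alignments(p$introns)
  div <- divergence_table(aln)
  logl$n_genes_divergence <- nrow(div)
  say("divergence: ", nrow(div), " genes")

  snps_raw <- read_snps(p$vcf)
  mapped <- map_snps_to_introns(snps_raw, met$introns)
  logl$n_snps <- nrow(snps_raw)
  logl$n_snps_outside_introns <- mapped$n_outside
  dvt <- diversity_table(aln, mapped$snps, div, denominator = denominator)
  say("diversity: ", nrow(dvt), " genes, ", nrow(mapped$snps),
      " intronic SNPs (", mapped$n_outside, " outside introns)")

  cds <- read_cds_fasta(p$cds)
  opp <- opportunity_table(cds, gm$transcripts, divergence = div,
                           snp_density = dvt)
  logl$n_genes_opportunity <- nrow(opp)
  say("opportunity: ", nrow(opp), " genes")

  covs <- read_tsv(p$covariates)
  cls <- read_tsv(p$classes)
  names(cls)[names(cls) == "class"] <- "disease_class"

  tabs <- list(met$lengths, div,
               dvt[, c("gene_id", "pi_all", "pi_cpg", "pi_noncpg",
                       "genealogy_length", "mean_maf", "n_snps")],
               opp, cls, covs)
  gene_table <- Reduce(function(a, b) merge(a, b, by = "gene_id"), tabs)
  logl$n_genes_joined <- nrow(gene_table)
  lost <- logl$n_genes_gff3 - nrow(gene_table)
  say("join: ", nrow(gene_table), " genes (", lost, " lost across stages)")

  sex <- gene_table$chromosome %in% exclude_chromosomes
  logl$n_sex_excluded <- sum(sex)
  gene_table <- gene_table[!sex, , drop = FALSE]
  say("sex-chromosome filter: ", sum(sex), " genes excluded, ",
      nrow(gene_table), " remain")

  report <- run_report(gene_table, log_log = log_log, pooled_t = pooled_t)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(gene_table, file.path(out_dir, "gene_table.tsv"))
    write_tsv(report_as_table(report), file.path(out_dir, "report.tsv"))
    jsonlite::write_json(.report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sink(file.path(out_dir, "report.txt")); print(report); sink()
    manifest <- list(
      package_version = as.character(packageVersion("dga")),
      r_version = R.version.string,
      inputs = p,
      input_md5 = as.list(tools::md5sum(unlist(p))),
      log = logl)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(gene_table = gene_table, report = report, log = logl)
}

.report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "dga_regression")) return(unclass(x))
    if (is.list(x)) return(lapply(x, strip))
    if (is.table(x)) return(as.list(x))
    x
  }
  strip(unclass(report))
}
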