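## Format adapters: GFF3, BED12, FASTA, VCF, TSV.
##
## Internal coordinates are 0-based half-open everywhere; conversions to
## the 1-based closed GFF3/VCF conventions happen only in this file. A
## gene model is a plain list of three tables (genes, transcripts, cds);
## write-then-read reproduces it exactly, and writing the re-read model
## again is byte-stable.

#' Construct a gene model container
#'
#' @param genes `data.frame` with `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` (0-based half-open gene span).
#' @param transcripts `data.frame` with `transcript_id`, `gene_id`.
#' @param cds `data.frame` with `transcript_id`, `chromosome`, `start`,
#'   `end` (0-based half-open CDS pieces), `strand`.
#' @return list of class `dga_genemodel`.
#' @export
gene_model <- function(genes, transcripts, cds) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(genes)),
            all(c("transcript_id", "gene_id") %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(cds)))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(cds$strand)) cds$strand <- "+"
  if (is.null(cds$chromosome))
    cds$chromosome <- genes$chromosome[match(
      transcripts$gene_id[match(cds$transcript_id, transcripts$transcript_id)],
      genes$gene_id)]
  structure(list(genes = genes, transcripts = transcripts, cds = cds),
            class = "dga_genemodel")
}

#' @export
print.dga_genemodel <- function(x, ...) {
  cat("<dga_genemodel> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$cds), " CDS pieces\n",
      sep = "")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Understands `gene` / `mRNA` / `CDS` features linked by `ID`/`Parent`
#' attributes. GFF3's 1-based closed intervals are converted to the
#' internal 0-based half-open convention on read.
#'
#' @param path GFF3 file.
#' @return a [gene_model()].
#' @export
read_gff3_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  ty <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- as.character(sapply(gr$Parent, function(p)
    if (length(p)) p[1] else NA_character_))
  gi <- ty == "gene"
  mi <- ty %in% c("mRNA", "transcript")
  ci <- ty == "CDS"
  if (!any(gi) || !any(mi) || !any(ci))
    stop("GFF3 '", path, "' lacks gene/mRNA/CDS features")
  genes <- data.frame(
    gene_id = ids[gi],
    chromosome = as.character(seqnames(gr))[gi],
    strand = as.character(strand(gr))[gi],
    start = start(gr)[gi] - 1L, end = end(gr)[gi],
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "+"
  transcripts <- data.frame(
    transcript_id = ids[mi], gene_id = parent[mi], stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = parent[ci],
    chromosome = as.character(seqnames(gr))[ci],
    start = start(gr)[ci] - 1L, end = end(gr)[ci],
    strand = as.character(strand(gr))[ci],
    stringsAsFactors = FALSE)
  cds$strand[cds$strand == "*"] <- "+"
  if (anyNA(transcripts$gene_id) || anyNA(cds$transcript_id))
    stop("GFF3 '", path, "': mRNA/CDS features without Parent attribute")
  gene_model(genes, transcripts, cds)
}

#' Write gene models as GFF3
#'
#' Deterministic writer (gene order preserved, transcripts and CDS pieces
#' sorted within parent), converting back to 1-based closed coordinates.
#'
#' @param gm a [gene_model()].
#' @param path output file.
#' @export
write_gff3_genes <- function(gm, path) {
  stopifnot(inherits(gm, "dga_genemodel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tx_by_gene <- split(gm$transcripts$transcript_id, gm$transcripts$gene_id)
  cds_by_tx <- split(gm$cds[, c("chromosome", "start", "end", "strand")],
                     gm$cds$transcript_id)
  out <- vector("list", nrow(gm$genes))
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    lines <- sprintf("%s\tdga\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chromosome,
                     g$start + 1L, g$end, g$strand, g$gene_id)
    for (tx in sort(tx_by_gene[[g$gene_id]])) {
      cc <- cds_by_tx[[tx]]
      cc <- cc[order(cc$start), , drop = FALSE]
      lens <- cc$end - cc$start
      phase <- if (g$strand == "+")
        (3L - (cumsum(c(0L, head(lens, -1L))) %% 3L)) %% 3L
      else rev((3L - (cumsum(c(0L, head(rev(lens), -1L))) %% 3L)) %% 3L)
      lines <- c(lines,
        sprintf("%s\tdga\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                g$chromosome, min(cc$start) + 1L, max(cc$end), g$strand, tx,
                g$gene_id),
        sprintf("%s\tdga\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                cc$chromosome, cc$start + 1L, cc$end, cc$strand, phase, tx, tx))
    }
    out[[i]] <- lines
  }
  writeLines(unlist(out), con)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Each BED12 line becomes one transcript whose blocks are taken as CDS
#' pieces; the `name` field is `transcript_id`, and the gene id is the name
#' stripped of a trailing `.t<k>` suffix (or the name itself). BED's
#' 0-based half-open convention matches the internal one.
#'
#' @param path BED12 file.
#' @return a [gene_model()].
#' @export
read_bed12_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e)))
  bl <- gr$blocks
  if (is.null(bl)) stop("BED file '", path, "' has no block (BED12) columns")
  tx_id <- as.character(gr$name)
  gene_id <- sub("\\.t[0-9]+$", "", tx_id)
  nb <- S4Vectors::elementNROWS(bl)
  blu <- unlist(bl)
  cds <- data.frame(
    transcript_id = rep(tx_id, nb),
    chromosome = rep(as.character(seqnames(gr)), nb),
    # blocks are 1-based closed relative to the (1-based) record start
    start = rep(start(gr) - 1L, nb) + start(blu) - 1L,
    end = rep(start(gr) - 1L, nb) + end(blu),
    strand = rep(as.character(strand(gr)), nb),
    stringsAsFactors = FALSE)
  cds$strand[cds$strand == "*"] <- "+"
  transcripts <- unique(data.frame(transcript_id = tx_id, gene_id = gene_id,
                                   stringsAsFactors = FALSE))
  agg_min <- tapply(start(gr) - 1L, gene_id, min)
  agg_max <- tapply(end(gr), gene_id, max)
  gids <- names(agg_min)
  genes <- data.frame(
    gene_id = gids,
    chromosome = as.character(seqnames(gr))[match(gids, gene_id)],
    strand = as.character(strand(gr))[match(gids, gene_id)],
    start = as.integer(agg_min), end = as.integer(agg_max),
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "+"
  gene_model(genes, transcripts, cds)
}

#' Read paired intron alignments from FASTA
#'
#' Expects two records per gene named `geneID|human` and `geneID|chimp`.
#'
#' @param path FASTA file.
#' @return named list of [intron_alignment()] objects.
#' @export
read_intron_alignments <- function(path) {
  x <- readDNAStringSet(path)
  nm <- names(x)
  parts <- strsplit(nm, "|", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1L)
  sp <- vapply(parts, `[`, character(1), 2L)
  if (anyNA(sp)) stop("FASTA records must be named geneID|species")
  hu <- which(sp == "human"); ch <- which(sp == "chimp")
  if (length(hu) != length(ch))
    stop("unpaired records in ", path, ": ", length(hu), " human vs ",
         length(ch), " chimp")
  chimp_of <- setNames(ch, gene[ch])
  seqs <- unname(as.character(x))
  out <- vector("list", length(hu))
  for (i in seq_along(hu)) {
    g <- gene[hu[i]]
    j <- chimp_of[[g]]
    if (is.null(j)) stop("no chimp record for gene ", g)
    out[[i]] <- intron_alignment(g, seqs[hu[i]], seqs[j])
  }
  names(out) <- gene[hu]
  out
}

#' Read SNPs from VCF
#'
#' Biallelic single-nucleotide records only: multi-allelic records are
#' skipped with a warning (`multiallelic = "split"` expands them instead,
#' one row per ALT, each keeping its own AF), and indels are dropped with
#' a tally. The ALT allele frequency comes from `INFO/AF`, falling back to
#' `AC/AN` when AF is absent; a record with neither is an error.
#'
#' @param path VCF file.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @return `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`, `af`.
#' @export
read_snps <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  info <- VariantAnnotation::info(vcf)
  af <- if ("AF" %in% names(info)) info$AF else NULL
  if (is.null(af)) {
    if (!all(c("AC", "AN") %in% names(info)))
      stop("VCF '", path, "' has neither INFO/AF nor INFO/AC+AN")
    ac <- info$AC; an <- info$AN
    af <- lapply(seq_along(ac), function(i) unlist(ac[[i]]) / an[[i]])
  }
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  multi <- n_alt > 1L
  if (any(multi) && multiallelic == "skip") {
    warning("skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep1 <- if (multiallelic == "skip") !multi else rep(TRUE, length(ref))
  alt_all <- as.character(unlist(altl))
  row_of <- rep(seq_along(ref), n_alt)
  keep_allele <- keep1[row_of]
  arow <- row_of[keep_allele]
  aalt <- alt_all[keep_allele]
  aaf <- unlist(af[keep1], use.names = FALSE)
  if (length(aaf) != length(aalt))
    stop("VCF '", path, "': AF entries do not match ALT alleles")
  out <- data.frame(chrom = chrom[arow], pos = pos[arow], ref = ref[arow],
                    alt = aalt, af = as.numeric(aaf),
                    stringsAsFactors = FALSE)
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$alt %in% c("A", "C", "G", "T")
  if (any(!snv))
    warning("dropping ", sum(!snv), " non-SNV record(s)")
  out[snv, , drop = FALSE]
}

#' Read transcript CDS sequences from FASTA
#'
#' @param path FASTA of in-frame CDS sequences, one record per transcript.
#' @return named character vector.
#' @export
read_cds_fasta <- function(path) {
  x <- readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' TSV helpers
#'
#' Thin `data.table` wrappers used across the pipeline (tab-separated,
#' unquoted, header preserved even when column names contain spaces).
#'
#' @param path file path.
#' @param x table to write.
#' @return `read_tsv()`: a `data.frame`.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", check.names = FALSE),
                check.names = FALSE)
}
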