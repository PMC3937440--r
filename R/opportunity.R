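## Weighted non-synonymous mutational-opportunity counting.
##
## Each CDS position is assigned mutation-spectrum weights: at CpG sites
## all mutations are assumed to be transitions (weight 1 on the single
## transition); elsewhere 60% of mutations are transitions (weight 0.6)
## and each transversion gets weight 0.2. The opportunity of a position is
## the summed weight of the alternates that change the encoded amino acid
## (stop gain/loss counts as a change). Totals are split by CpG status and
## combined with class-specific intron divergence (or SNP density) to
## predict per-site and genic non-synonymous mutation rates.

#' Mutation-spectrum weights for the three alternates of a base
#'
#' At a CpG site all mutations are transitions: the single alternate is the
#' transition (C>T or G>A) with weight 1. At non-CpG sites the transition
#' carries weight 0.6 and each transversion 0.2. Weights always sum to 1.
#'
#' @param base one of `A,C,G,T`.
#' @param is_cpg logical; CpG positions must be C or G.
#' @return `data.frame` with columns `alt` and `weight`.
#' @export
site_mutation_weights <- function(base, is_cpg = FALSE) {
  if (!base %in% c("A", "C", "G", "T")) stop("invalid base: ", base)
  if (is_cpg) {
    if (!base %in% c("C", "G"))
      stop("CpG positions are C or G by definition; got ", base)
    return(data.frame(alt = .TRANSITION[[base]], weight = 1.0,
                      stringsAsFactors = FALSE))
  }
  data.frame(alt = c(.TRANSITION[[base]], .TRANSVERSIONS[[base]]),
             weight = c(0.6, 0.2, 0.2), stringsAsFactors = FALSE)
}

#' CpG status of CDS positions given flanking bases
#'
#' Positions are classified on the coding strand using the spliced CDS
#' sequence plus the immediately adjacent transcript bases. A terminal C
#' (or leading G) whose deciding neighbour is an unknown flank cannot be
#' classified; such positions are treated as non-CpG and tallied.
#'
#' @keywords internal
#' @noRd
.cds_cpg_status <- function(x, left_flank, right_flank) {
  n <- length(x)
  isC <- x == charToRaw("C"); isG <- x == charToRaw("G")
  r_ok <- !is.na(right_flank) && right_flank %in% c("A", "C", "G", "T")
  l_ok <- !is.na(left_flank) && left_flank %in% c("A", "C", "G", "T")
  rightG <- c(isG[-1], r_ok && identical(right_flank, "G"))
  leftC <- c(l_ok && identical(left_flank, "C"), isC[-n])
  is_cpg <- (isC & rightG) | (isG & leftC)
  unknown <- ((isC & c(rep(FALSE, n - 1), !r_ok)) |
              (isG & c(!l_ok, rep(FALSE, n - 1))))
  # unknown-context C/G that did not classify as CpG via the other test
  unknown <- unknown & !is_cpg
  list(is_cpg = is_cpg, n_unknown_context = sum(unknown))
}

#' Weighted non-synonymous opportunity of one transcript CDS
#'
#' Enumerates, for every CDS position, the weighted single-base changes
#' (see [site_mutation_weights()]) that alter the encoded amino acid under
#' the standard genetic code, and accumulates the weights into CpG and
#' non-CpG totals. The terminal stop codon must be excluded by the caller;
#' the first codon need not be ATG.
#'
#' @param cds_seq in-frame CDS sequence (string over `A,C,G,T`, length a
#'   positive multiple of 3, no terminal stop).
#' @param left_flank,right_flank single base adjacent to the CDS in the
#'   transcript, or `NA` if unknown. Unknown flanks make the adjacent
#'   position's CpG status undecidable; it is then treated as non-CpG and
#'   counted in `n_unknown_context`.
#' @param allow_internal_stop if `TRUE`, an internal stop codon is skipped
#'   with a warning instead of raising an error.
#' @return list with `o_cpg`, `o_noncpg` (weighted opportunities),
#'   `n_cpg_positions`, `n_noncpg_positions`, `cds_length`,
#'   `n_unknown_context`.
#' @export
transcript_opportunity <- function(cds_seq, left_flank = NA, right_flank = NA,
                                   allow_internal_stop = FALSE) {
  .init_code_tables()
  stopifnot(is.character(cds_seq), length(cds_seq) == 1L)
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n == 0L) stop("empty CDS sequence")
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  x <- charToRaw(cds_seq)
  if (is.null(.dga$acgt_ok)) {
    tab <- logical(256)
    tab[as.integer(charToRaw("ACGT")) + 1L] <- TRUE
    .dga$acgt_ok <- tab
  }
  if (!all(.dga$acgt_ok[as.integer(x) + 1L]))
    stop("CDS sequence contains non-ACGT characters")
  codon_str <- substring(cds_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  ci <- match(codon_str, names(.dga$code))
  aa <- .dga$code[ci]
  stops <- which(aa == "*")
  keep_codon <- rep(TRUE, length(ci))
  if (length(stops)) {
    if (!allow_internal_stop)
      stop("internal stop codon at codon ", stops[1])
    warning("skipping ", length(stops), " internal stop codon(s)")
    keep_codon[stops] <- FALSE
  }
  st <- .cds_cpg_status(x,
                        if (is.na(left_flank)) NA else toupper(left_flank),
                        if (is.na(right_flank)) NA else toupper(right_flank))
  is_cpg <- st$is_cpg
  pos_codon <- rep(ci, each = 3L)
  pos_in_codon <- rep(1:3, length.out = n)
  pos_keep <- rep(keep_codon, each = 3L)
  ns_ts <- .dga$ns_ts[cbind(pos_codon, pos_in_codon)]
  ns_tv <- .dga$ns_tv[cbind(pos_codon, pos_in_codon)]
  w_cpg <- ifelse(is_cpg & pos_keep, ns_ts, 0)
  w_non <- ifelse(!is_cpg & pos_keep, 0.6 * ns_ts + 0.2 * ns_tv, 0)
  list(o_cpg = sum(w_cpg),
       o_noncpg = sum(w_non),
       n_cpg_positions = sum(is_cpg & pos_keep),
       n_noncpg_positions = sum(!is_cpg & pos_keep),
       cds_length = n,
       n_unknown_context = st$n_unknown_context)
}

#' Average opportunity counts over a gene's transcripts
#'
#' Genes with multiple transcripts get the unweighted arithmetic mean of
#' every opportunity field across transcripts.
#'
#' @param per_transcript list of records from [transcript_opportunity()].
#' @return a single averaged record (same fields).
#' @export
gene_opportunity <- function(per_transcript) {
  if (length(per_transcript) == 0L) stop("no transcript records supplied")
  if (!is.null(names(per_transcript)) && "o_cpg" %in% names(per_transcript))
    per_transcript <- list(per_transcript)
  fields <- c("o_cpg", "o_noncpg", "n_cpg_positions", "n_noncpg_positions",
              "cds_length", "n_unknown_context")
  out <- lapply(fields, function(f)
    mean(vapply(per_transcript, `[[`, numeric(1), f)))
  setNames(out, fields)
}

#' Predicted non-synonymous mutation rate from intron divergence
#'
#' The expected non-synonymous mutation rate per CDS site is the CpG
#' fraction of non-synonymous opportunity times the CpG intron divergence
#' plus the non-CpG fraction times the non-CpG divergence. The genic rate
#' weights the divergences by the absolute opportunities instead.
#'
#' @param opportunity record from [gene_opportunity()].
#' @param d_cpg,d_noncpg per-site intron divergences by class (or a
#'   divergence record with those fields passed as `d_cpg`).
#' @return list with `p_cpg`, `rate_per_site`, `rate_genic`.
#' @export
predicted_nonsyn_rate <- function(opportunity, d_cpg, d_noncpg = NULL) {
  if (is.list(d_cpg) || is.data.frame(d_cpg)) {
    d_noncpg <- d_cpg$d_noncpg
    d_cpg <- d_cpg$d_cpg
  }
  tot <- opportunity$o_cpg + opportunity$o_noncpg
  if (!is.finite(tot) || tot <= 0)
    return(list(p_cpg = NA_real_, rate_per_site = NA_real_,
                rate_genic = NA_real_))
  p_cpg <- opportunity$o_cpg / tot
  if (is.null(d_cpg) || is.null(d_noncpg) || is.na(d_cpg) || is.na(d_noncpg))
    return(list(p_cpg = p_cpg, rate_per_site = NA_real_, rate_genic = NA_real_))
  list(p_cpg = p_cpg,
       rate_per_site = p_cpg * d_cpg + (1 - p_cpg) * d_noncpg,
       rate_genic = opportunity$o_cpg * d_cpg + opportunity$o_noncpg * d_noncpg)
}

#' Predicted non-synonymous population mutation rate from SNP densities
#'
#' Weights the intronic SNP densities at CpG and non-CpG sites by the CpG
#' fraction of non-synonymous opportunity.
#'
#' @param opportunity record from [gene_opportunity()].
#' @param snp_density_cpg,snp_density_noncpg intronic SNP densities
#'   (SNPs/site) by class.
#' @return predicted theta per non-synonymous site (scalar; `NA` when the
#'   total opportunity is zero).
#' @export
predicted_nonsyn_theta <- function(opportunity, snp_density_cpg,
                                   snp_density_noncpg) {
  tot <- opportunity$o_cpg + opportunity$o_noncpg
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  if (is.na(snp_density_cpg) || is.na(snp_density_noncpg)) return(NA_real_)
  p_cpg <- opportunity$o_cpg / tot
  p_cpg * snp_density_cpg + (1 - p_cpg) * snp_density_noncpg
}

#' Per-gene opportunity and predicted-rate table
#'
#' Computes transcript opportunities for every transcript CDS, averages
#' within genes, and (optionally) joins per-gene divergence and SNP-density
#' records to produce predicted rates. A terminal stop codon, if present,
#' is stripped before counting.
#'
#' @param cds_seqs named character vector of transcript CDS sequences; names
#'   are transcript ids.
#' @param tx2gene `data.frame` with columns `transcript_id`, `gene_id`.
#' @param divergence optional per-gene divergence table
#'   ([divergence_table()]).
#' @param snp_density optional per-gene density table with `pi_cpg`,
#'   `pi_noncpg` (see [diversity_table()]).
#' @param allow_internal_stop forwarded to [transcript_opportunity()].
#' @return `data.frame` with one row per gene.
#' @export
opportunity_table <- function(cds_seqs, tx2gene, divergence = NULL,
                              snp_density = NULL, allow_internal_stop = FALSE) {
  .init_code_tables()
  stopifnot(all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  gid <- tx2gene$gene_id[match(names(cds_seqs), tx2gene$transcript_id)]
  if (anyNA(gid))
    stop("transcripts without gene mapping: ",
         paste(head(names(cds_seqs)[is.na(gid)]), collapse = ", "))
  per_tx <- lapply(cds_seqs, function(s) {
    s <- .strip_terminal_stop(s)
    transcript_opportunity(s, allow_internal_stop = allow_internal_stop)
  })
  genes <- unique(gid)
  by_gene <- split(per_tx, factor(gid, levels = genes))
  ops <- lapply(by_gene, gene_opportunity)
  o_cpg <- vapply(ops, `[[`, numeric(1), "o_cpg")
  o_non <- vapply(ops, `[[`, numeric(1), "o_noncpg")
  tot <- o_cpg + o_non
  p_cpg <- ifelse(tot > 0, o_cpg / tot, NA_real_)
  if (!is.null(divergence)) {
    i <- match(genes, divergence$gene_id)
    d_cpg <- divergence$d_cpg[i]
    d_non <- divergence$d_noncpg[i]
  } else d_cpg <- d_non <- rep(NA_real_, length(genes))
  rate_per_site <- p_cpg * d_cpg + (1 - p_cpg) * d_non
  rate_genic <- o_cpg * d_cpg + o_non * d_non
  rate_genic[is.na(p_cpg)] <- NA_real_
  if (!is.null(snp_density)) {
    i <- match(genes, snp_density$gene_id)
    theta <- p_cpg * snp_density$pi_cpg[i] + (1 - p_cpg) * snp_density$pi_noncpg[i]
  } else theta <- rep(NA_real_, length(genes))
  data.frame(gene_id = genes, o_cpg = o_cpg, o_noncpg = o_non,
             p_cpg = p_cpg, rate_per_site = rate_per_site,
             rate_genic = rate_genic, theta_pred = theta,
             n_unknown_context = vapply(ops, `[[`, numeric(1),
                                        "n_unknown_context"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
.strip_terminal_stop <- function(s) {
  .init_code_tables()
  n <- nchar(s)
  if (n >= 3L && n %% 3L == 0L) {
    last <- toupper(substr(s, n - 2L, n))
    if (!is.na(.dga$code[last]) && .dga$code[[last]] == "*")
      return(substr(s, 1L, n - 3L))
  }
  s
}
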