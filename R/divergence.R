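## CpG site classification and human-chimp intron divergence counting.
##
## Divergence is used as a per-site mutation-rate proxy. Sites are
## stratified into CpG and non-CpG classes because methylated CpGs are
## hypermutable; no multiple-hit correction is applied (divergence is ~1%,
## so the correction would be negligible).

.ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

.raw_lookup <- function(chars) vapply(chars, function(ch) charToRaw(ch), raw(1))

# 256-entry membership table for the alignment alphabet (raw %in% raw would
# coerce to character, which is slow at genome scale)
.aln_ok_table <- function() {
  if (is.null(.dga$aln_ok)) {
    tab <- logical(256)
    tab[as.integer(charToRaw("ACGTN-")) + 1L] <- TRUE
    .dga$aln_ok <- tab
  }
  .dga$aln_ok
}

#' Construct an intron alignment object
#'
#' A pairwise (human/chimp) gapped alignment of a gene's introns plus a
#' per-column exon mask. Sequences must have equal length over the alphabet
#' `A,C,G,T,N,-` (case-insensitive; soft-masked lowercase is accepted and
#' uppercased).
#'
#' @param gene_id gene identifier.
#' @param human,chimp gapped sequences as single strings.
#' @param exon_mask optional logical vector, one element per alignment
#'   column; `TRUE` marks exonic (masked) columns. Defaults to all `FALSE`.
#' @return an object of class `dga_alignment`.
#' @export
intron_alignment <- function(gene_id, human, chimp, exon_mask = NULL) {
  stopifnot(is.character(human), length(human) == 1L,
            is.character(chimp), length(chimp) == 1L)
  human <- toupper(human); chimp <- toupper(chimp)
  if (nchar(human) != nchar(chimp))
    stop("alignment sequences differ in length for gene ", gene_id)
  for (s in c(human, chimp)) {
    bad <- regmatches(s, regexpr("[^ACGTN-]", s))
    if (length(bad) && nzchar(bad))
      stop("illegal character '", bad, "' at position ",
           regexpr("[^ACGTN-]", s), " in alignment for gene ", gene_id)
  }
  n <- nchar(human)
  if (is.null(exon_mask)) exon_mask <- rep(FALSE, n)
  if (length(exon_mask) != n)
    stop("exon_mask length (", length(exon_mask),
         ") != alignment length (", n, ") for gene ", gene_id)
  structure(list(gene_id = gene_id, human = human, chimp = chimp,
                 exon_mask = as.logical(exon_mask)),
            class = "dga_alignment")
}

#' @export
print.dga_alignment <- function(x, ...) {
  cat("<dga_alignment> gene ", x$gene_id, ": ", nchar(x$human),
      " columns, ", sum(x$exon_mask), " masked\n", sep = "")
  invisible(x)
}

#' Classify alignment columns as CpG / non-CpG / unclassifiable
#'
#' Classification uses the human sequence only. A column is CpG iff its
#' human base is a C immediately followed by G, or a G immediately preceded
#' by C, *ignoring gap columns* when locating the neighbour (an indel in the
#' chimp lineage does not break a human CpG dinucleotide). Columns that are
#' gaps or N, or whose deciding neighbour is N or off the end of the
#' sequence (a terminal C with no right neighbour, a leading G with no left
#' neighbour), are unclassifiable. A and T bases never need a neighbour and
#' are always non-CpG.
#'
#' @param human_seq gapped human sequence (single string, `A,C,G,T,N,-`).
#' @return integer vector, one element per column: `1` = CpG, `0` =
#'   non-CpG, `NA` = unclassifiable.
#' @export
classify_cpg <- function(human_seq) {
  stopifnot(is.character(human_seq), length(human_seq) == 1L)
  x <- charToRaw(toupper(human_seq))
  bad <- !.aln_ok_table()[as.integer(x) + 1L]
  if (any(bad))
    stop("illegal character '", rawToChar(x[which(bad)[1]]),
         "' at position ", which(bad)[1])
  n <- length(x)
  out <- rep(NA_integer_, n)
  if (n == 0L) return(out)
  keep <- x != charToRaw("-")
  xs <- x[keep]
  m <- length(xs)
  if (m == 0L) return(out)
  isC <- xs == charToRaw("C")
  isG <- xs == charToRaw("G")
  isN <- xs == charToRaw("N")
  rightG <- c(isG[-1], FALSE)
  rightN <- c(isN[-1], TRUE)   # off the right end behaves like unknown
  leftC <- c(FALSE, isC[-m])
  leftN <- c(TRUE, isN[-m])    # off the left end behaves like unknown
  cls <- integer(m)            # default: non-CpG (A, T, decidable C/G)
  cls[isC & rightG] <- 1L
  cls[isC & !rightG & rightN] <- NA_integer_
  cls[isG & leftC] <- 1L
  cls[isG & !leftC & leftN] <- NA_integer_
  cls[isN] <- NA_integer_
  out[keep] <- cls
  out
}

#' Mask exonic columns of an alignment
#'
#' Marks every alignment column whose *human ungapped* coordinate falls in
#' one of the supplied intervals. Intervals are 0-based half-open in human
#' sequence coordinates. Gap columns in the human sequence carry no human
#' base and are never masked.
#'
#' @param alignment a [intron_alignment()] object.
#' @param exon_intervals list (or 2-column matrix) of `c(start, end)`
#'   half-open 0-based intervals.
#' @return the alignment with an updated exon mask.
#' @export
apply_exon_mask <- function(alignment, exon_intervals) {
  stopifnot(inherits(alignment, "dga_alignment"))
  if (is.matrix(exon_intervals))
    exon_intervals <- lapply(seq_len(nrow(exon_intervals)),
                             function(i) exon_intervals[i, ])
  if (length(exon_intervals) == 0L) return(alignment)
  x <- charToRaw(alignment$human)
  keep <- x != charToRaw("-")
  coord <- cumsum(keep) - 1L           # human 0-based coordinate per column
  ulen <- sum(keep)
  mask <- alignment$exon_mask
  for (iv in exon_intervals) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > ulen || iv[1] > iv[2])
      stop("exon interval [", iv[1], ",", iv[2],
           ") out of range for human length ", ulen)
    mask <- mask | (keep & coord >= iv[1] & coord < iv[2])
  }
  alignment$exon_mask <- mask
  alignment
}

#' Count divergent sites by CpG class
#'
#' Counts only columns that are unmasked, ungapped in both sequences, non-N
#' in both, and CpG-classifiable (see [classify_cpg()]). A difference is a
#' case-insensitive base mismatch; no multiple-hit correction is applied.
#'
#' @param alignment a [intron_alignment()] object.
#' @return list with fields `cpg_sites`, `noncpg_sites`, `cpg_diffs`,
#'   `noncpg_diffs`.
#' @export
count_divergence <- function(alignment) {
  stopifnot(inherits(alignment, "dga_alignment"))
  h <- charToRaw(alignment$human)
  c2 <- charToRaw(alignment$chimp)
  cls <- classify_cpg(alignment$human)
  gap <- charToRaw("-"); nn <- charToRaw("N")
  usable <- !alignment$exon_mask &
    h != gap & c2 != gap & h != nn & c2 != nn & !is.na(cls)
  diff <- usable & (h != c2)
  cpg <- usable & !is.na(cls) & cls == 1L
  # cls NA already excluded by `usable`; the !is.na above guards NA algebra
  list(cpg_sites = sum(cpg),
       noncpg_sites = sum(usable & cls == 0L, na.rm = TRUE),
       cpg_diffs = sum(diff & cls == 1L, na.rm = TRUE),
       noncpg_diffs = sum(diff & cls == 0L, na.rm = TRUE))
}

#' Pool site-class counts into a per-gene divergence record
#'
#' Aggregation across a gene's introns is *pooled*: summed differences are
#' divided by summed sites per class, so every site carries equal weight
#' (not the mean of per-intron ratios). A class with zero usable sites gets
#' a missing (`NA`) divergence, never zero.
#'
#' @param counts list of count records from [count_divergence()].
#' @param gene_id gene identifier carried into the record.
#' @return one-row `data.frame` with `gene_id`, `d_cpg`, `d_noncpg`,
#'   `d_all`, `sites_cpg`, `sites_noncpg`.
#' @export
gene_divergence <- function(counts, gene_id = NA_character_) {
  if (length(counts) == 0L) stop("no count records supplied")
  if (!is.null(names(counts)) && "cpg_sites" %in% names(counts))
    counts <- list(counts)
  s_cpg <- sum(vapply(counts, `[[`, numeric(1), "cpg_sites"))
  s_non <- sum(vapply(counts, `[[`, numeric(1), "noncpg_sites"))
  d_cpg_n <- sum(vapply(counts, `[[`, numeric(1), "cpg_diffs"))
  d_non_n <- sum(vapply(counts, `[[`, numeric(1), "noncpg_diffs"))
  data.frame(
    gene_id = gene_id,
    d_cpg = if (s_cpg > 0) d_cpg_n / s_cpg else NA_real_,
    d_noncpg = if (s_non > 0) d_non_n / s_non else NA_real_,
    d_all = if (s_cpg + s_non > 0) (d_cpg_n + d_non_n) / (s_cpg + s_non) else NA_real_,
    sites_cpg = s_cpg,
    sites_noncpg = s_non,
    stringsAsFactors = FALSE)
}

#' Per-gene divergence table for a set of alignments
#'
#' Runs [count_divergence()] and [gene_divergence()] over a list of
#' alignments (one or more per gene; multiple alignments with the same
#' `gene_id` are pooled).
#'
#' @param alignments list of [intron_alignment()] objects.
#' @return `data.frame` with one row per gene.
#' @export
divergence_table <- function(alignments) {
  ids <- vapply(alignments, `[[`, character(1), "gene_id")
  counts <- lapply(alignments, count_divergence)
  take <- function(f) vapply(counts, `[[`, numeric(1), f)
  g <- factor(ids, levels = unique(ids))
  s_cpg <- as.numeric(rowsum(take("cpg_sites"), g))
  s_non <- as.numeric(rowsum(take("noncpg_sites"), g))
  d_cpg_n <- as.numeric(rowsum(take("cpg_diffs"), g))
  d_non_n <- as.numeric(rowsum(take("noncpg_diffs"), g))
  data.frame(
    gene_id = levels(g),
    d_cpg = ifelse(s_cpg > 0, d_cpg_n / s_cpg, NA_real_),
    d_noncpg = ifelse(s_non > 0, d_non_n / s_non, NA_real_),
    d_all = ifelse(s_cpg + s_non > 0,
                   (d_cpg_n + d_non_n) / (s_cpg + s_non), NA_real_),
    sites_cpg = s_cpg, sites_noncpg = s_non,
    stringsAsFactors = FALSE)
}
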