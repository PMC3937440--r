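## Standard genetic code and precomputed non-synonymous opportunity tables.
##
## The code table is hard-coded here (TCAG order, first codon position
## slowest) so the implementation does not share a code path with the
## Biostrings-based oracle used in the tests.

.CODE_BASES <- c("T", "C", "A", "G")

.AA_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' All 64 codons in TCAG enumeration order
#' @keywords internal
#' @noRd
.codon_table <- function() {
  cods <- character(64)
  k <- 0L
  for (b1 in .CODE_BASES) for (b2 in .CODE_BASES) for (b3 in .CODE_BASES) {
    k <- k + 1L
    cods[k] <- paste0(b1, b2, b3)
  }
  setNames(strsplit(.AA_STRING, "")[[1]], cods)
}

#' Translate a codon using the built-in standard-code table ('*' = stop)
#' @keywords internal
#' @noRd
.translate_codon <- function(codon) {
  aa <- .dga$code[codon]
  if (any(is.na(aa))) stop("not a codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Build lookup arrays used by transcript_opportunity():
#'   ns_ts[codon, pos]  - 1 if the transition at that position is non-synonymous
#'   ns_tv[codon, pos]  - number (0..2) of non-synonymous transversions
#' A change to or from a stop codon counts as non-synonymous.
#' @keywords internal
#' @noRd
.build_opportunity_tables <- function() {
  code <- .dga$code
  cods <- names(code)
  ns_ts <- matrix(0, nrow = 64, ncol = 3, dimnames = list(cods, NULL))
  ns_tv <- matrix(0, nrow = 64, ncol = 3, dimnames = list(cods, NULL))
  for (ci in seq_along(cods)) {
    cod <- strsplit(cods[ci], "")[[1]]
    aa0 <- code[[cods[ci]]]
    for (p in 1:3) {
      b <- cod[p]
      alt <- cod; alt[p] <- .TRANSITION[[b]]
      if (code[[paste(alt, collapse = "")]] != aa0) ns_ts[ci, p] <- 1
      for (tv in .TRANSVERSIONS[[b]]) {
        alt <- cod; alt[p] <- tv
        if (code[[paste(alt, collapse = "")]] != aa0) ns_tv[ci, p] <- ns_tv[ci, p] + 1
      }
    }
  }
  list(ns_ts = ns_ts, ns_tv = ns_tv)
}

.init_code_tables <- function() {
  if (!is.null(.dga$code)) return(invisible())
  .dga$code <- .codon_table()
  tabs <- .build_opportunity_tables()
  .dga$ns_ts <- tabs$ns_ts
  .dga$ns_tv <- tabs$ns_tv
  .dga$base_raw <- charToRaw("ACGT")
  invisible()
}

.onLoad <- function(libname, pkgname) {
  .init_code_tables()
}
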