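# Independent brute-force oracles. These deliberately avoid the package's
# lookup-table / vectorized code paths: translation goes through
# Biostrings::GENETIC_CODE and everything is enumerated column by column.

# --- genetic-code oracle -----------------------------------------------------

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# CpG status of position i in seq given flanks (character scalars or NA)
oracle_cds_cpg <- function(chars, i, left, right) {
  n <- length(chars)
  nb_right <- if (i < n) chars[i + 1] else right
  nb_left <- if (i > 1) chars[i - 1] else left
  (identical(chars[i], "C") && identical(nb_right, "G")) ||
    (identical(chars[i], "G") && identical(nb_left, "C"))
}

# brute-force transcript opportunity: mutate every position to every base,
# translate, compare
oracle_transcript_opportunity <- function(cds, left = NA, right = NA) {
  chars <- strsplit(cds, "")[[1]]
  n <- length(chars)
  o_cpg <- 0; o_non <- 0; n_cpg <- 0L
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) {
    cpg <- oracle_cds_cpg(chars, i, left, right)
    if (cpg) n_cpg <- n_cpg + 1L
    ci <- (i - 1) %/% 3
    cod <- paste(chars[ci * 3 + 1:3], collapse = "")
    aa0 <- oracle_translate(cod)
    for (alt in setdiff(c("A", "C", "G", "T"), chars[i])) {
      mut <- chars; mut[i] <- alt
      cod2 <- paste(mut[ci * 3 + 1:3], collapse = "")
      changed <- oracle_translate(cod2) != aa0
      if (cpg) {
        if (alt == ts[[chars[i]]] && changed) o_cpg <- o_cpg + 1.0
      } else {
        w <- if (alt == ts[[chars[i]]]) 0.6 else 0.2
        if (changed) o_non <- o_non + w
      }
    }
  }
  list(o_cpg = o_cpg, o_noncpg = o_non, n_cpg_positions = n_cpg,
       n_noncpg_positions = n - n_cpg)
}

# --- divergence oracle -------------------------------------------------------

# column-by-column enumerator following the stated classification rule
oracle_count_divergence <- function(human, chimp, mask = NULL) {
  h <- strsplit(toupper(human), "")[[1]]
  c2 <- strsplit(toupper(chimp), "")[[1]]
  n <- length(h)
  if (is.null(mask)) mask <- rep(FALSE, n)
  # ungapped human with column back-pointers
  hb <- h[h != "-"]
  col_of <- which(h != "-")
  cls <- rep(NA, n)  # TRUE=cpg, FALSE=noncpg, NA=unclassifiable
  for (k in seq_along(hb)) {
    b <- hb[k]
    if (b == "N") next
    if (b == "C") {
      rt <- if (k < length(hb)) hb[k + 1] else "?"
      cls[col_of[k]] <- if (rt == "G") TRUE else if (rt %in% c("N", "?")) NA
        else FALSE
    } else if (b == "G") {
      lt <- if (k > 1) hb[k - 1] else "?"
      cls[col_of[k]] <- if (lt == "C") TRUE else if (lt %in% c("N", "?")) NA
        else FALSE
    } else cls[col_of[k]] <- FALSE
  }
  out <- c(cpg_sites = 0, noncpg_sites = 0, cpg_diffs = 0, noncpg_diffs = 0)
  for (i in seq_len(n)) {
    if (mask[i] || is.na(cls[i])) next
    if (h[i] %in% c("-", "N") || c2[i] %in% c("-", "N")) next
    d <- h[i] != c2[i]
    if (cls[i]) {
      out["cpg_sites"] <- out["cpg_sites"] + 1
      if (d) out["cpg_diffs"] <- out["cpg_diffs"] + 1
    } else {
      out["noncpg_sites"] <- out["noncpg_sites"] + 1
      if (d) out["noncpg_diffs"] <- out["noncpg_diffs"] + 1
    }
  }
  lapply(as.list(out), as.integer)
}

random_alignment <- function(ncol, p_gap = 0.08, p_n = 0.03, p_diff = 0.1) {
  draw <- function() {
    x <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
    x[runif(ncol) < p_n] <- "N"
    x[runif(ncol) < p_gap] <- "-"
    x
  }
  h <- draw()
  c2 <- h
  flip <- runif(ncol) < p_diff
  c2[flip] <- sample(c("A", "C", "G", "T", "N", "-"), sum(flip), replace = TRUE)
  list(human = paste(h, collapse = ""), chimp = paste(c2, collapse = ""))
}

# --- permutation oracles -----------------------------------------------------

perm_t_p <- function(a, b, n_perm = 4000) {
  obs <- abs(welch_t_test(a, b)$t)
  x <- c(a, b); na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(length(x), na)
    t <- abs(welch_t_test(x[idx], x[-idx])$t)
    if (t >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

perm_F_p <- function(values, classes, n_perm = 4000) {
  obs <- one_way_anova(values, classes)$F
  hits <- 0L
  for (i in seq_len(n_perm)) {
    f <- one_way_anova(values, sample(classes))$F
    if (f >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
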