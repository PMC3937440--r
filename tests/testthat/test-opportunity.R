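# Non-synonymous mutational-opportunity counting.

test_that("site_mutation_weights encodes the mutation spectrum", {
  w <- site_mutation_weights("C", is_cpg = TRUE)
  expect_equal(w$alt, "T"); expect_equal(w$weight, 1.0)
  w <- site_mutation_weights("G", is_cpg = TRUE)
  expect_equal(w$alt, "A")
  w <- site_mutation_weights("A", is_cpg = FALSE)
  expect_equal(w$alt, c("G", "C", "T"))
  expect_equal(w$weight, c(0.6, 0.2, 0.2))
  expect_equal(sum(w$weight), 1)
  expect_error(site_mutation_weights("A", is_cpg = TRUE), "C or G")
  expect_error(site_mutation_weights("X"), "invalid base")
})

test_that("transcript_opportunity matches hand-enumerated codons", {
  # ATG: every change to Met is non-synonymous; per-position weights sum to 1
  atg <- transcript_opportunity("ATG")
  expect_equal(atg$o_noncpg, 3.0)
  expect_equal(atg$o_cpg, 0)
  expect_equal(oracle_transcript_opportunity("ATG")$o_noncpg, 3.0)

  # CGA: pos1 C (CpG, transition C>T -> TGA stop, non-syn, weight 1);
  # pos2 G (CpG, transition G>A -> CAA Gln, non-syn, weight 1);
  # pos3 A: CGN all code Arg -> synonymous
  cga <- transcript_opportunity("CGA")
  expect_equal(cga$o_cpg, 2.0)
  expect_equal(cga$o_noncpg, 0)
  expect_equal(oracle_transcript_opportunity("CGA")$o_cpg, 2.0)

  expect_error(transcript_opportunity(""), "empty")
  expect_error(transcript_opportunity("ACGTA"), "multiple of 3")
  expect_error(transcript_opportunity("TAAATG"), "internal stop")
  expect_warning(out <- transcript_opportunity("TAAATG",
                                               allow_internal_stop = TRUE),
                 "skipping")
  expect_equal(out$o_noncpg, transcript_opportunity("ATG")$o_noncpg)
})

test_that("flanks decide CpG status at the CDS edges", {
  # trailing C becomes CpG when the right flank is G
  with_g <- transcript_opportunity("ATC", right_flank = "G")
  without <- transcript_opportunity("ATC")
  expect_equal(with_g$n_cpg_positions, 1)
  expect_equal(without$n_cpg_positions, 0)
  expect_equal(without$n_unknown_context, 1)  # trailing C, unknown right
  expect_equal(with_g$n_unknown_context, 0)
  # leading G becomes CpG when the left flank is C
  expect_equal(transcript_opportunity("GAT", left_flank = "C")$n_cpg_positions,
               1)
  # known non-G flank: decidable, no tally
  known <- transcript_opportunity("ATC", right_flank = "A")
  expect_equal(known$n_unknown_context, 0)
  expect_equal(known$n_cpg_positions, 0)
})

test_that("duplicating a CDS doubles the opportunity exactly", {
  set.seed(3)
  for (i in 1:20) {
    cds <- paste(sample(c("GCT", "ATG", "CGA", "TTT", "CAC", "GGA"),
                        sample(2:6, 1), replace = TRUE), collapse = "")
    a <- transcript_opportunity(cds)
    b <- transcript_opportunity(paste0(cds, cds))
    # interior positions double exactly; the junction can add CpG context,
    # so compare with flanks fixed to neutral A
    a2 <- transcript_opportunity(cds, left_flank = "A", right_flank = "A")
    b2 <- transcript_opportunity(paste0(cds, cds), left_flank = "A",
                                 right_flank = "A")
    first <- substr(cds, 1, 1); last <- substr(cds, nchar(cds), nchar(cds))
    if (last == "C" || first == "G") next  # junction changes classes; skip
    expect_equal(b2$o_cpg, 2 * a2$o_cpg)
    expect_equal(b2$o_noncpg, 2 * a2$o_noncpg)
  }
})

test_that("per-position opportunity is bounded by 1 and 4-fold sites give 0", {
  # invariant o <= n positions over random CDS
  set.seed(4)
  for (i in 1:30) {
    cds <- paste(sample(names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"], 5, replace = TRUE), collapse = "")
    op <- transcript_opportunity(cds)
    expect_lte(op$o_cpg, op$n_cpg_positions)
    expect_lte(op$o_noncpg, op$n_noncpg_positions)
  }
  # fourfold-degenerate third positions contribute nothing: every GGN codes
  # glycine, so all nine third-position changes of GGG are synonymous
  for (alt in c("A", "C", "T"))
    expect_equal(oracle_translate(paste0("GG", alt)), "G")
  op_ggg <- transcript_opportunity("GGG", left_flank = "A", right_flank = "A")
  op_gg <- oracle_transcript_opportunity("GGG", "A", "A")
  expect_equal(op_ggg$o_noncpg, op_gg$o_noncpg)
  # positions 1 and 2 account for all of it (weights 0.6/0.2 in position 1,
  # and in position 2 only some changes are non-synonymous)
  expect_gt(op_ggg$o_noncpg, 0)
})

test_that("gene_opportunity averages across transcripts", {
  t1 <- transcript_opportunity("ATG")            # o_noncpg 3
  t2 <- list(o_cpg = 0, o_noncpg = 5, n_cpg_positions = 0,
             n_noncpg_positions = 6, cds_length = 6, n_unknown_context = 0)
  avg <- gene_opportunity(list(t1, t2))
  expect_equal(avg$o_noncpg, 4)
  expect_equal(avg$cds_length, 4.5)
  expect_equal(gene_opportunity(list(t1))$o_noncpg, 3)
  expect_equal(gene_opportunity(t1)$o_noncpg, 3)   # bare record accepted
  expect_error(gene_opportunity(list()), "no transcript")
  # averaging preserves o <= n positions
  set.seed(5)
  for (i in 1:20) {
    recs <- replicate(3, {
      o <- runif(2); n <- o + runif(2)
      list(o_cpg = o[1], o_noncpg = o[2], n_cpg_positions = n[1],
           n_noncpg_positions = n[2], cds_length = 10, n_unknown_context = 0)
    }, simplify = FALSE)
    g <- gene_opportunity(recs)
    expect_lte(g$o_cpg, g$n_cpg_positions)
    expect_lte(g$o_noncpg, g$n_noncpg_positions)
  }
})

test_that("predicted rates combine opportunity and divergence", {
  op <- list(o_cpg = 2, o_noncpg = 8)
  pr <- predicted_nonsyn_rate(op, d_cpg = 0.02, d_noncpg = 0.008)
  expect_equal(pr$p_cpg, 0.2)
  expect_equal(pr$rate_per_site, 0.2 * 0.02 + 0.8 * 0.008)  # 0.0104
  expect_equal(pr$rate_genic, 2 * 0.02 + 8 * 0.008)         # 0.104
  # equal class divergences collapse to that divergence
  pr2 <- predicted_nonsyn_rate(op, 0.01, 0.01)
  expect_equal(pr2$rate_per_site, 0.01)
  # zero opportunity -> missing
  pr3 <- predicted_nonsyn_rate(list(o_cpg = 0, o_noncpg = 0), 0.01, 0.01)
  expect_true(is.na(pr3$rate_per_site))
  # missing class divergence -> rate missing, p_cpg still reported
  pr4 <- predicted_nonsyn_rate(op, NA_real_, 0.008)
  expect_true(is.na(pr4$rate_per_site))
  expect_equal(pr4$p_cpg, 0.2)
})

test_that("predicted theta weights SNP densities by CpG opportunity", {
  op <- list(o_cpg = 5, o_noncpg = 5)
  expect_equal(predicted_nonsyn_theta(op, 0.002, 0.001), 0.0015)
  expect_equal(predicted_nonsyn_theta(op, 0.001, 0.001), 0.001)
  expect_true(is.na(predicted_nonsyn_theta(list(o_cpg = 0, o_noncpg = 0),
                                           0.002, 0.001)))
})

test_that("opportunity_table averages transcripts and joins divergence", {
  cds <- c(gX.t1 = "ATGGCT", gX.t2 = "ATG", gY.t1 = "CGA")
  tx2gene <- data.frame(transcript_id = names(cds),
                        gene_id = c("gX", "gX", "gY"))
  div <- data.frame(gene_id = c("gX", "gY"), d_cpg = c(0.02, 0.02),
                    d_noncpg = c(0.008, 0.008))
  tab <- opportunity_table(cds, tx2gene, divergence = div)
  expect_equal(tab$gene_id, c("gX", "gY"))
  o1 <- transcript_opportunity("ATGGCT")$o_noncpg
  o2 <- transcript_opportunity("ATG")$o_noncpg
  expect_equal(tab$o_noncpg[1], (o1 + o2) / 2)
  expect_equal(tab$p_cpg[2], 1)   # CGA is all-CpG opportunity
  expect_equal(tab$rate_per_site[2], 0.02)
  # terminal stop codons are stripped before counting
  tab2 <- opportunity_table(c(gZ.t1 = "ATGTAA"),
                            data.frame(transcript_id = "gZ.t1",
                                       gene_id = "gZ"))
  expect_equal(tab2$o_noncpg, transcript_opportunity("ATG")$o_noncpg)
})
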