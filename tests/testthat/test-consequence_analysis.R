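test_that("apply_edits substitutes exactly and checks reference bases", {
  g <- gene_record("g", "AAAGGGCCC")
  expect_identical(apply_edits(g, manual_sites(g, integer(0), character(0))),
                   g$seq)
  s <- manual_sites(g, 0, "G")
  expect_identical(apply_edits(g, s), "GAAGGGCCC")
  s_bad <- s
  s_bad$dna_base <- "C"
  expect_error(apply_edits(g, s_bad), "mismatch")
  # round trip against the simulator's own edited transcript
  cfg <- simulation_config(seed = 17, n_edits = 30)
  mc <- make_minicircle(cfg)
  pe <- plant_edits(mc$gene, cfg)
  s2 <- manual_sites(mc$gene, pe$edits$position, pe$edits$rna_base)
  expect_identical(apply_edits(mc$gene, s2), pe$transcript)
})

test_that("codon effects are evaluated jointly within a codon", {
  # ATG edited at positions 1 and 2 becomes GCG: Met -> Ala, both sites
  # non-synonymous
  g <- gene_record("g", "ATGAAA")
  s <- manual_sites(g, c(0, 1), c("G", "C"))
  a <- annotate_codon_effects(g, s)
  expect_equal(a$ref_codon, c("ATG", "ATG"))
  expect_equal(a$alt_codon, c("GCG", "GCG"))
  expect_equal(a$ref_aa, c("M", "M"))
  expect_equal(a$alt_aa, c("A", "A"))
  expect_false(any(a$synonymous))
  expect_equal(a$codon_position, c(1, 2))
  # TGA with A->G at codon position 3 restores Trp
  g2 <- gene_record("g2", "AAATGAAAA")
  s2 <- manual_sites(g2, 5, "G")
  a2 <- annotate_codon_effects(g2, s2)
  expect_equal(a2$ref_aa, "*")
  expect_equal(a2$alt_aa, "W")
  expect_true(a2$stop_restoration)
  # third-position CCA -> CCG is synonymous
  g3 <- gene_record("g3", "CCAAAA")
  a3 <- annotate_codon_effects(g3, manual_sites(g3, 2, "G"))
  expect_true(a3$synonymous)
  expect_false(a3$stop_restoration)
  expect_error(annotate_codon_effects(g3, manual_sites(g3, 2, "G") |>
                                        transform(position = 99,
                                                  cds_position = 99)),
               "beyond")
})

test_that("joint-codon annotation matches a brute-force whole-sequence oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n_codons <- sample(5:30, 1)
    g <- gene_record("g", random_cds_oracle(n_codons))
    chars <- strsplit(g$seq, "")[[1]]
    n_edit <- sample(1:6, 1)
    pos <- sort(sample(seq_along(chars), n_edit)) - 1L
    alt <- vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"), chars[p + 1]), 1), character(1))
    s <- manual_sites(g, pos, alt)
    a <- annotate_codon_effects(g, s)
    # oracle: translate whole sequences and compare codon by codon
    edited <- chars
    edited[pos + 1] <- alt
    pre_aa <- translate_cds(g$seq)
    post_aa <- translate_cds(paste(edited, collapse = ""))
    for (i in seq_len(nrow(a))) {
      ci <- a$codon_index[i] + 1
      expect_equal(a$ref_aa[i], substr(pre_aa, ci, ci))
      expect_equal(a$alt_aa[i], substr(post_aa, ci, ci))
      expect_equal(a$synonymous[i],
                   substr(pre_aa, ci, ci) == substr(post_aa, ci, ci))
    }
  }
})

test_that("summarize_gene reproduces printed-table arithmetic", {
  # frequencies are count/length at one decimal, half-up
  g <- gene_record("petD_like", random_cds_oracle(159))
  expect_equal(nchar(g$seq), 477)
  cfg <- simulation_config(seed = 23, gene_length_nt = 477, n_edits = 33)
  pe <- plant_edits(g, cfg)
  s <- annotate_codon_effects(g, manual_sites(g, pe$edits$position,
                                              pe$edits$rna_base))
  summ <- summarize_gene(g, s)
  expect_equal(summ$edit_frequency_pct, 6.9)
  expect_equal(summ$n_edits, 33)
  expect_equal(sum(summ[, edit_types()$label]), 33)
  expect_lte(summ$n_aa_substitutions, summ$n_edits)
  # zero sites give an all-zero summary
  s0 <- annotate_codon_effects(g, manual_sites(g, integer(0), character(0)))
  summ0 <- summarize_gene(g, s0)
  expect_equal(summ0$n_edits, 0)
  expect_equal(summ0$edit_frequency_pct, 0)
  expect_equal(summ0$n_aa_substitutions, 0)
})

test_that("aggregate_stats reproduces published derived statistics from the fixture", {
  fx <- table1_fixture()
  names(fx)[names(fx) == "gene"] <- "gene_id"
  agg <- aggregate_stats(fx)
  expect_equal(agg$total_edits, 471)
  expect_equal(agg$total_mrna_edits, 413)
  expect_equal(agg$total_aa_substitutions, 364)
  expect_equal(agg$pct_aa_changing, 88)
  # per-gene G/C transversion shares: petB 9/23 = 39%, petD 8/33 = 24%
  petB <- fx[fx$gene_id == "petB", ]
  petD <- fx[fx$gene_id == "petD", ]
  expect_equal(round_half_up(100 * petB$`G/C` / petB$n_edits), 39)
  expect_equal(round_half_up(100 * petD$`G/C` / petD$n_edits), 24)
  # exactly the nine observed type categories are non-zero
  observed <- names(agg$type_totals)[agg$type_totals > 0]
  expect_setequal(observed, c("A/G", "G/A", "C/U", "U/C", "G/C",
                              "G/U", "U/G", "A/C", "A/U"))
  # A/G dominates the spectrum
  expect_equal(names(which.max(agg$type_spectrum_pct)), "A/G")
})

test_that("aggregate GC shift and codon-position stats come from the sites", {
  g <- gene_record("g", paste(rep("AAA", 40), collapse = ""))
  s <- annotate_codon_effects(g, manual_sites(g, 3, "G"))
  summ <- summarize_gene(g, s)
  agg <- aggregate_stats(summ, s, genes = list(g))
  expect_equal(agg$gc_pre_pct, 0)
  expect_equal(agg$gc_post_pct, round(100 * 1 / 120, 2), tolerance = 1e-6)
  expect_equal(unname(agg$codon_position_counts), c(1, 0, 0))
  # double substitutions at codon positions 1+2 are counted as site pairs
  g2 <- gene_record("g2", "ATGAAAAAAATG")
  s2 <- annotate_codon_effects(g2, manual_sites(g2, c(0, 1, 6), c("G", "C", "G")))
  agg2 <- aggregate_stats(summarize_gene(g2, s2), s2, genes = list(g2))
  expect_equal(agg2$double_substitution_pct, round_half_up(100 * 2 / 3, 1))
})

test_that("identity_to_homolog measures global alignment identity", {
  p <- random_protein(100)
  expect_equal(unname(identity_to_homolog(p, p, p)), c(100, 100))
  # pre differs at 5 of 100 positions, post at 2 -> (95, 98)
  mutate_at <- function(p, idx) {
    ch <- strsplit(p, "")[[1]]
    for (i in idx) ch[i] <- setdiff(c("A", "G", "V", "L"), ch[i])[1]
    paste(ch, collapse = "")
  }
  set.seed(5)
  idx <- sample(100, 5)
  pre <- mutate_at(p, idx)
  post <- mutate_at(p, idx[1:2])
  out <- identity_to_homolog(pre, post, p)
  expect_equal(unname(out), c(95, 98))
  expect_error(identity_to_homolog("", "A", "A"), "empty")
})

test_that("hydropathy_mw_shift tracks single-residue substitutions exactly", {
  # Ile -> Val (ATA -> GTA): gravy decreases by (4.5-4.2)/len, MW drops
  g <- gene_record("g", "ATGATAAAA")
  s <- annotate_codon_effects(g, manual_sites(g, 3, "G"))
  sh <- hydropathy_mw_shift(g, s)
  expect_equal(sh$gravy_post - sh$gravy_pre, (4.2 - 4.5) / 3,
               tolerance = 1e-12)
  expect_lt(sh$mw_post, sh$mw_pre)
  # Thr -> Ala (ACA -> GCA): gravy increases by (1.8 - (-0.7))/len
  g2 <- gene_record("g2", "ATGACAAAA")
  s2 <- annotate_codon_effects(g2, manual_sites(g2, 3, "G"))
  sh2 <- hydropathy_mw_shift(g2, s2)
  expect_equal(sh2$gravy_post - sh2$gravy_pre, (1.8 - (-0.7)) / 3,
               tolerance = 1e-12)
  # no edits: pre == post
  s0 <- annotate_codon_effects(g, manual_sites(g, integer(0), character(0)))
  sh0 <- hydropathy_mw_shift(g, s0)
  expect_equal(sh0$mw_pre, sh0$mw_post)
  expect_equal(sh0$gravy_pre, sh0$gravy_post)
  # premature stops are stripped and flagged, not fatal
  g3 <- gene_record("g3", "ATGTGAAAA")
  s3 <- annotate_codon_effects(g3, manual_sites(g3, 5, "G"))
  sh3 <- hydropathy_mw_shift(g3, s3)
  expect_true(sh3$premature_stop_pre)
  expect_false(sh3$premature_stop_post)
})

test_that("spearman_rank matches brute-force rank-Pearson and stats::cor.test", {
  expect_equal(spearman_rank(1:3, 3:1)$rho, -1)
  expect_equal(spearman_rank(1:3, c(10, 20, 30))$rho, 1)
  set.seed(77)
  for (i in 1:100) {
    x <- stats::runif(12)
    y <- stats::runif(12)
    if (i %% 3 == 0) x[1:4] <- x[5]  # exercise tie handling
    sp <- spearman_rank(x, y)
    rho_oracle <- stats::cor(rank(x), rank(y))
    expect_equal(sp$rho, rho_oracle, tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
    # t-approximation p-value oracle
    tstat <- rho_oracle * sqrt(10 / (1 - rho_oracle^2))
    expect_equal(sp$p_value, 2 * stats::pt(-abs(tstat), 10),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rank(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})
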