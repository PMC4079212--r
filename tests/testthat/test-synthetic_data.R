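test_that("simulation_config validates fractions, lengths and spectrum", {
  expect_error(simulation_config(gene_length_nt = 1000), "multiple of 3")
  expect_error(simulation_config(edited_fraction = 1.5), "fractions")
  expect_error(simulation_config(rna_coverage = 0), "positive")
  expect_error(simulation_config(type_spectrum = c("A/G" = 0)),
               "not all zero")
  expect_error(simulation_config(type_spectrum = c("X/Y" = 1)), "unknown")
})

test_that("make_minicircle plants consistent IRs, a unique motif, and is seed-deterministic", {
  cfg <- simulation_config(seed = 1)
  mc <- make_minicircle(cfg)
  chars <- strsplit(mc$seq, "")[[1]]
  expect_equal(length(mc$truth$ir_coordinates), 17)
  for (ir in mc$truth$ir_coordinates) {
    left <- paste(chars[(ir$left[1] + 1):ir$left[2]], collapse = "")
    right <- paste(chars[(ir$right[1] + 1):ir$right[2]], collapse = "")
    expect_identical(left, revcomp(right))
    expect_gte(ir$arm_gc_pct, 70)
    expect_gte(ir$arm_length_nt, 8)
  }
  # motif occurs at the recorded position and nowhere else
  hits <- gregexpr(cfg$motif, mc$seq, fixed = TRUE)[[1]]
  expect_equal(as.integer(hits), mc$truth$motif_position + 1L)
  # layout: promoter < TSS < motif < CDS
  expect_lt(mc$truth$promoter_position, mc$truth$tss_position)
  expect_lt(mc$truth$tss_position, mc$truth$motif_position)
  expect_lt(mc$truth$motif_position, mc$truth$cds_span[1])
  # the V region between TSS and motif is 1-41 nt
  vlen <- mc$truth$motif_position - mc$truth$tss_position
  expect_true(vlen >= 1 && vlen <= 41)
  # CDS matches the gene record and is in frame
  expect_identical(substr(mc$seq, mc$truth$cds_span[1] + 1,
                          mc$truth$cds_span[2]), mc$gene$seq)
  expect_false(grepl("*", translate_cds(mc$gene$seq), fixed = TRUE))
  # determinism
  mc2 <- make_minicircle(cfg)
  expect_identical(mc$seq, mc2$seq)
  mc3 <- make_minicircle(simulation_config(seed = 2))
  expect_false(identical(mc$seq, mc3$seq))
})

test_that("plant_edits respects count, spectrum and base compatibility", {
  cfg <- simulation_config(seed = 5, n_edits = 10,
                           type_spectrum = c("A/G" = 1))
  mc <- make_minicircle(cfg)
  pe <- plant_edits(mc$gene, cfg)
  expect_equal(nrow(pe$edits), 10)
  expect_true(all(pe$edits$dna_base == "A"))
  expect_true(all(pe$edits$rna_base == "G"))
  expect_true(all(pe$edits$label == "A/G"))
  expect_false(any(duplicated(pe$edits$position)))
  tchars <- strsplit(pe$transcript, "")[[1]]
  expect_true(all(tchars[pe$edits$position + 1] == "G"))
  # zero edits leaves the reference untouched
  cfg0 <- simulation_config(seed = 5, n_edits = 0)
  expect_identical(plant_edits(mc$gene, cfg0)$transcript, mc$gene$seq)
  # reference bases always match the gene at planted positions
  gchars <- strsplit(mc$gene$seq, "")[[1]]
  expect_identical(gchars[pe$edits$position + 1], pe$edits$dna_base)
})

test_that("plant_edits reproduces table-style edit frequency arithmetic", {
  # 33 edits on a 477-nt gene is a 6.9% edit frequency
  cfg <- simulation_config(seed = 9, gene_length_nt = 477, n_edits = 33)
  mc <- make_minicircle(cfg)
  pe <- plant_edits(mc$gene, cfg)
  sites <- manual_sites(mc$gene, pe$edits$position, pe$edits$rna_base)
  sites <- annotate_codon_effects(mc$gene, sites)
  summ <- summarize_gene(mc$gene, sites)
  expect_equal(summ$edit_frequency_pct, 6.9)
})

test_that("plant_edits errors when the spectrum cannot be placed", {
  g <- gene_record("allA", "ATGAAAAAAAAA")
  cfg <- simulation_config(seed = 1, n_edits = 5,
                           type_spectrum = c("G/A" = 1))
  expect_error(plant_edits(g, cfg), "exceeds eligible|incompatible")
})

test_that("simulate_reads hits target coverage and honours roles", {
  cfg <- simulation_config(seed = 7, gene_length_nt = 1200)
  mc <- make_minicircle(cfg)
  pe <- plant_edits(mc$gene, cfg)
  edits_mc <- pe$edits
  edits_mc$position <- edits_mc$position + mc$truth$cds_span[1]
  truth <- mc$truth
  truth$planted_edits <- edits_mc
  rna <- simulate_reads(mc$seq, truth, cfg, "RNA")
  dna <- simulate_reads(mc$seq, truth, cfg, "DNA")
  # mean depth within 10% of 300
  depth <- sum(nchar(rna$seq)) / nchar(mc$seq)
  expect_true(abs(depth - 300) / 300 < 0.1)
  expect_true(all(rna$start >= 0))
  expect_true(all(rna$start + nchar(rna$seq) <= nchar(mc$seq)))
  # error-free, edited_fraction 1: every overlapping RNA read shows the
  # edited base; DNA reads never do
  rp <- build_pileup(rna, mc$seq)
  dp <- build_pileup(dna, mc$seq)
  for (i in seq_len(nrow(edits_mc))) {
    pos <- edits_mc$position[i]
    alt <- edits_mc$rna_base[i]
    ref <- edits_mc$dna_base[i]
    rcol <- pileup_column(rp, pos)
    expect_equal(sum(rcol$base_counts[alt, ]), rcol$depth)
    dcol <- pileup_column(dp, pos)
    expect_equal(sum(dcol$base_counts[ref, ]), dcol$depth)
  }
  # determinism / seed sensitivity
  rna2 <- simulate_reads(mc$seq, truth, cfg, "RNA")
  expect_identical(rna, rna2)
  cfg2 <- simulation_config(seed = 8)
  expect_false(identical(simulate_reads(mc$seq, truth, cfg2, "RNA")$seq,
                         rna$seq))
  expect_error(simulate_reads("ACGT", truth, cfg, "RNA"), "read_length")
})

test_that("partial editing yields roughly the configured edited fraction", {
  cfg <- simulation_config(seed = 13, n_edits = 12, edited_fraction = 0.6)
  sim <- simulate_minicircle_experiment(cfg)
  rp <- build_pileup(sim$rna_reads, sim$seq)
  fr <- vapply(seq_len(nrow(sim$truth$planted_edits)), function(i) {
    col <- pileup_column(rp, sim$truth$planted_edits$position[i])
    sum(col$base_counts[sim$truth$planted_edits$rna_base[i], ]) / col$depth
  }, numeric(1))
  expect_true(abs(mean(fr) - 0.6) < 0.05)
})

test_that("SAM round trip is faithful", {
  cfg <- simulation_config(seed = 3, rna_coverage = 20,
                           gene_length_nt = 300)
  mc <- make_minicircle(cfg)
  rna <- simulate_reads(mc$seq, mc$truth, cfg, "RNA")
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(rna, tmp, nchar(mc$seq))
  back <- read_sam(tmp)
  expect_equal(back$start, rna$start)
  expect_equal(back$strand, rna$strand)
  expect_equal(back$seq, rna$seq)
  lines <- readLines(tmp)
  expect_true(any(grepl("^@SQ\tSN:", lines)))
  expect_true(all(grepl("^\\d+M$",
                        sapply(strsplit(lines[!startsWith(lines, "@")], "\t"),
                               `[[`, 6))))
})

test_that("the packaged count table has consistent published totals", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 14)
  expect_equal(sum(fx$n_edits), 471)
  petD <- fx[fx$gene == "petD", ]
  expect_equal(petD$n_edits, 33)
  expect_equal(petD$cds_length_nt, 477)
  expect_equal(petD$n_aa_substitutions, 28)
  expect_equal(petD$protein_length_aa, 159)
  psbA <- fx[fx$gene == "psbA", ]
  expect_equal(psbA$n_edits, 4)
  expect_equal(psbA$cds_length_nt, 1029)
  # per-type counts sum to the row totals wherever they are known
  type_cols <- c("A/G", "G/A", "C/U", "U/C", "G/C", "G/U", "U/G", "A/C", "A/U")
  known <- stats::complete.cases(fx[, type_cols])
  expect_equal(rowSums(fx[known, type_cols]), fx$n_edits[known],
               ignore_attr = TRUE)
  # the flagged 16S row stores only its total
  expect_true(all(is.na(fx[fx$gene == "16S_rRNA", type_cols])))
  # alternative start codons are carried for the three known genes
  expect_equal(fx$start_override[fx$gene == "psbI"], "TTG")
  expect_equal(fx$start_override[fx$gene == "petD"], "ATA")
  expect_equal(fx$start_override[fx$gene == "psaB"], "TTT")
})
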