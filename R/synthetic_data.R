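# Synthetic minicircle and read simulator with recorded ground truth.
#
# The generator emulates haploid organellar sequencing data: a single-gene
# minicircle whose AT-rich core carries GC-rich inverted repeats and the
# conserved CACCAATGCACC RNA-binding motif, high roughly-uniform coverage
# (default 300-fold), near-zero DNA polymorphism, and planted editing events
# drawn from a configurable 12-category substitution spectrum.

#' Simulation configuration
#'
#' Defaults encode the conditions of the system being emulated: ~300-fold
#' RNA and DNA coverage, 100-nt reads, a 1200-nt gene at ~37% GC (plastid
#' ORFs of peridinin dinoflagellates are AT-rich), 15-20 GC-rich inverted
#' repeats in the core (default 17), complete editing of each site
#' (\code{edited_fraction} 1), and an editing-type spectrum matching the
#' observed plastid spectrum (A/G-dominant, ~55%).
#'
#' @param seed integer master seed; every simulator operation is
#'   deterministic given the config.
#' @param gene_length_nt CDS length, multiple of 3.
#' @param gene_gc_fraction target GC fraction of the CDS, 0-1.
#' @param n_edits number of editing events to plant.
#' @param edit_frequency optional fraction of CDS positions to edit;
#'   overrides \code{n_edits} when set.
#' @param type_spectrum named non-negative weights over editing-type labels
#'   (U notation, e.g. "A/G"); unnamed types get weight 0.
#' @param edited_fraction per-read probability that an overlapping RNA read
#'   carries a planted edit (1 = complete editing).
#' @param rna_coverage,dna_coverage mean fold coverage.
#' @param read_length_nt read length.
#' @param sequencing_error_rate per-base i.i.d. substitution error rate.
#' @param strand_mix fraction of forward-strand reads.
#' @param n_snps number of low-level DNA polymorphisms to plant.
#' @param snp_alt_fraction fraction of molecules (DNA and RNA) carrying each
#'   planted SNP's alternate base.
#' @param cns_ir_count inverted repeats to embed in the core.
#' @param motif conserved core motif sequence.
#' @param exclude_start exclude the start codon from edit placement.
#' @param allow_stop_restoration permit planting edits that sit on reference
#'   stop codons (stop-restoration scenarios); also lifts the default
#'   exclusion of edits that would create a transcript stop.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              gene_length_nt = 1200L,
                              gene_gc_fraction = 0.37,
                              n_edits = 24L,
                              edit_frequency = NULL,
                              type_spectrum = default_type_spectrum(),
                              edited_fraction = 1.0,
                              rna_coverage = 300,
                              dna_coverage = 300,
                              read_length_nt = 100L,
                              sequencing_error_rate = 0,
                              strand_mix = 0.5,
                              n_snps = 0L,
                              snp_alt_fraction = 0.5,
                              cns_ir_count = 17L,
                              motif = "CACCAATGCACC",
                              exclude_start = TRUE,
                              allow_stop_restoration = FALSE) {
  cfg <- list(seed = as.integer(seed),
              gene_length_nt = as.integer(gene_length_nt),
              gene_gc_fraction = gene_gc_fraction,
              n_edits = as.integer(n_edits),
              edit_frequency = edit_frequency,
              type_spectrum = type_spectrum,
              edited_fraction = edited_fraction,
              rna_coverage = rna_coverage,
              dna_coverage = dna_coverage,
              read_length_nt = as.integer(read_length_nt),
              sequencing_error_rate = sequencing_error_rate,
              strand_mix = strand_mix,
              n_snps = as.integer(n_snps),
              snp_alt_fraction = snp_alt_fraction,
              cns_ir_count = as.integer(cns_ir_count),
              motif = motif,
              exclude_start = isTRUE(exclude_start),
              allow_stop_restoration = isTRUE(allow_stop_restoration))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  frac <- c(cfg$gene_gc_fraction, cfg$edited_fraction,
            cfg$sequencing_error_rate, cfg$strand_mix, cfg$snp_alt_fraction)
  if (any(frac < 0 | frac > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$gene_length_nt <= 0L || cfg$gene_length_nt %% 3L != 0L)
    stop("gene_length_nt must be a positive multiple of 3")
  if (cfg$rna_coverage <= 0 || cfg$dna_coverage <= 0)
    stop("coverage must be positive")
  if (cfg$read_length_nt <= 0L)
    stop("read_length_nt must be positive")
  if (any(cfg$type_spectrum < 0) || sum(cfg$type_spectrum) <= 0)
    stop("type_spectrum weights must be non-negative and not all zero")
  bad <- setdiff(names(cfg$type_spectrum), EDIT_TYPE_ORDER)
  if (length(bad))
    stop("unknown editing-type labels in spectrum: ", paste(bad, collapse = ","))
  invisible(cfg)
}

#' Default editing-type spectrum
#'
#' Weights follow the observed plastid editing spectrum: A/G dominates
#' (~55%), C/U and U/C ~13% each, G/A ~7%, G/C ~8%, and rare A/C, G/U, U/G,
#' A/U transversions. The three never-observed types carry weight 0 but may
#' be switched on.
#'
#' @return named numeric weights over the 12 type labels.
#' @export
default_type_spectrum <- function() {
  w <- c("A/G" = 55, "G/A" = 6.7, "C/U" = 13, "U/C" = 13,
         "G/C" = 8.3, "G/U" = 0.8, "U/G" = 0.4, "A/C" = 2.1, "A/U" = 0.4,
         "C/A" = 0, "C/G" = 0, "U/A" = 0)
  w[EDIT_TYPE_ORDER]
}

# Sample n bases with a target GC fraction.
sample_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Random CDS: ATG start then sense codons at the target GC.
random_cds <- function(length_nt, gc) {
  n_codons <- length_nt %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1L] <- "ATG"
  i <- 2L
  while (i <= n_codons) {
    cand <- chars_seq(sample_bases(3L, gc))
    if (!cand %in% stops) {
      codons[i] <- cand
      i <- i + 1L
    }
  }
  paste(codons, collapse = "")
}

# One GC-rich inverted repeat: left arm, AT-rich loop, right arm = revcomp.
random_ir <- function(min_arm = 8L, max_arm = 12L, min_loop = 3L,
                      max_loop = 10L) {
  repeat {
    arm_len <- sample(min_arm:max_arm, 1L)
    arm <- chars_seq(sample_bases(arm_len, 0.9))
    if (gc_content(arm) >= 75) break
  }
  loop_len <- sample(min_loop:max_loop, 1L)
  loop <- chars_seq(sample_bases(loop_len, 0.15))
  list(seq = paste0(arm, loop, revcomp(arm)), arm_len = arm_len,
       loop_len = loop_len,
       arm_gc_pct = gc_content(arm))
}

at_spacer <- function(min_len = 10L, max_len = 30L) {
  chars_seq(sample_bases(sample(min_len:max_len, 1L), 0.15))
}

#' Generate a synthetic minicircle with recorded feature truth
#'
#' Builds a single-gene minicircle: an AT-rich core carrying
#' \code{cns_ir_count} GC-rich inverted repeats (arm >= 8 nt, arm GC >= 70%)
#' in AT-rich spacers, a promoter-like element just upstream of the TSS, a
#' short variable spacer (1-41 nt) between the TSS and the conserved motif,
#' then the ORF (with terminal stop) and a short tail. The motif occurs
#' exactly once. All coordinates are 0-based half-open and recorded in the
#' returned truth object. Deterministic given \code{config$seed}.
#'
#' @param config a \code{simulation_config}.
#' @return list with \code{seq} (minicircle string), \code{gene}
#'   (\code{gene_record} for the CDS, with attribute "cds_start"), and
#'   \code{truth} (list: \code{ir_coordinates}, \code{motif_position},
#'   \code{promoter_position}, \code{tss_position}, \code{cds_span}).
#' @export
make_minicircle <- function(config) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 1L))
  for (attempt in 1:50) {
    parts <- character(0)
    irs <- list()
    cursor <- 0L
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    add(chars_seq(at_spacer(20L, 40L)))
    for (k in seq_len(config$cns_ir_count)) {
      ir <- random_ir()
      left_start <- cursor
      irs[[k]] <- list(
        left = c(left_start, left_start + ir$arm_len),
        right = c(left_start + ir$arm_len + ir$loop_len,
                  left_start + 2L * ir$arm_len + ir$loop_len),
        arm_length_nt = ir$arm_len, loop_length_nt = ir$loop_len,
        arm_gc_pct = ir$arm_gc_pct)
      add(ir$seq)
      add(chars_seq(at_spacer()))
    }
    promoter_position <- cursor
    add(chars_seq(sample_bases(25L, 0.3)))
    add(chars_seq(at_spacer(3L, 6L)))
    tss_position <- cursor
    add(chars_seq(sample_bases(sample(1:41, 1L), 0.15)))
    motif_position <- cursor
    add(config$motif)
    add(chars_seq(at_spacer(15L, 25L)))
    cds_start <- cursor
    cds <- random_cds(config$gene_length_nt, config$gene_gc_fraction)
    add(cds)
    cds_end <- cursor
    add("TAA")
    add(chars_seq(at_spacer(40L, 60L)))
    seq <- paste(parts, collapse = "")
    hits <- gregexpr(config$motif, seq, fixed = TRUE)[[1]]
    if (length(hits) == 1L && hits[1] == motif_position + 1L) break
    if (attempt == 50) stop("could not place motif uniquely")
  }
  gene <- gene_record("synth_gene", cds, molecule_class = "protein_coding")
  attr(gene, "cds_start") <- cds_start
  truth <- list(ir_coordinates = irs,
                motif_position = motif_position,
                promoter_position = promoter_position,
                tss_position = tss_position,
                cds_span = c(cds_start, cds_end),
                planted_edits = NULL, planted_snps = NULL)
  list(seq = seq, gene = gene, truth = truth)
}

#' Plant editing events on a gene with known truth
#'
#' Draws \code{n_edits} distinct CDS positions (uniformly, optionally
#' excluding the start codon) and assigns each an editing type from the
#' configured spectrum, restricted to types whose DNA base matches the
#' reference base at the drawn position. Unless
#' \code{allow_stop_restoration} is set, edits that would turn the edited
#' codon into a stop are excluded. Deterministic given \code{config$seed}.
#'
#' @param gene a \code{gene_record} (protein-coding uses codon-aware
#'   exclusions; rRNA genes only exclude nothing).
#' @param config a \code{simulation_config}; \code{edit_frequency}, if set,
#'   overrides \code{n_edits} as \code{round(frequency * CDS length)}.
#' @return list with \code{transcript} (edited sequence) and \code{edits}
#'   (data.frame: \code{position} 0-based on the gene, \code{dna_base},
#'   \code{rna_base} DNA alphabet, \code{label}).
#' @export
plant_edits <- function(gene, config) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 2L))
  chars <- seq_chars(gene$seq)
  n <- length(chars)
  n_edits <- if (!is.null(config$edit_frequency))
    as.integer(round(config$edit_frequency * n)) else config$n_edits
  types <- edit_types()
  w <- config$type_spectrum[types$label]
  w[is.na(w)] <- 0
  types$weight <- as.numeric(w)
  eligible <- seq_len(n)
  if (config$exclude_start && gene$molecule_class == "protein_coding")
    eligible <- setdiff(eligible, 1:3)
  # base compatibility: only positions whose base appears in the spectrum
  spectrum_bases <- unique(types$dna_base[types$weight > 0])
  eligible <- eligible[chars[eligible] %in% spectrum_bases]
  if (n_edits > length(eligible))
    stop("requested edit count exceeds eligible positions ",
         "(spectrum incompatible with reference composition?)")
  order_pos <- sample(eligible)
  chosen <- integer(0)
  chosen_alt <- character(0)
  chosen_label <- character(0)
  stops <- c("TAA", "TAG", "TGA")
  for (pos in order_pos) {
    if (length(chosen) >= n_edits) break
    ref <- chars[pos]
    cand <- types[types$dna_base == ref & types$weight > 0, ]
    if (!nrow(cand)) next
    if (gene$molecule_class == "protein_coding" &&
        !config$allow_stop_restoration) {
      ci <- (pos - 1L) %/% 3L
      codon <- chars[(ci * 3L + 1L):(ci * 3L + 3L)]
      off <- (pos - 1L) %% 3L + 1L
      ok <- vapply(cand$rna_base, function(rb) {
        codon2 <- codon
        codon2[off] <- chartr("U", "T", rb)
        !chars_seq(codon2) %in% stops
      }, logical(1))
      cand <- cand[ok, ]
      if (!nrow(cand)) next
    }
    pick <- cand[sample.int(nrow(cand), 1L, prob = cand$weight), ]
    chosen <- c(chosen, pos)
    chosen_alt <- c(chosen_alt, chartr("U", "T", pick$rna_base))
    chosen_label <- c(chosen_label, pick$label)
  }
  if (length(chosen) < n_edits)
    stop("could not place ", n_edits, " edits: spectrum incompatible with ",
         "reference composition")
  ord <- order(chosen)
  edits <- data.frame(position = chosen[ord] - 1L,
                      dna_base = chars[chosen][ord],
                      rna_base = chosen_alt[ord],
                      label = chosen_label[ord],
                      stringsAsFactors = FALSE)
  tchars <- chars
  tchars[edits$position + 1L] <- edits$rna_base
  list(transcript = chars_seq(tchars), edits = edits)
}

#' Plant low-level DNA polymorphisms
#'
#' Chooses \code{config$n_snps} template positions (outside \code{exclude})
#' and a random alternate base for each. SNPs model variation among organelle
#' genome copies: both DNA and RNA reads carry the alternate base with
#' probability \code{snp_alt_fraction}.
#'
#' @param template template DNA string.
#' @param config a \code{simulation_config}.
#' @param exclude 0-based positions to avoid (e.g. planted edit positions).
#' @return data.frame: \code{position} (0-based), \code{ref_base},
#'   \code{alt_base}.
#' @export
plant_snps <- function(template, config, exclude = integer(0)) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 3L))
  chars <- seq_chars(template)
  pool <- setdiff(seq_along(chars), exclude + 1L)
  if (config$n_snps > length(pool)) stop("too many SNPs requested")
  pos <- sort(sample(pool, config$n_snps))
  alt <- vapply(pos, function(p) sample(setdiff(DNA_BASES, chars[p]), 1L),
                character(1))
  data.frame(position = pos - 1L, ref_base = chars[pos], alt_base = alt,
             stringsAsFactors = FALSE)
}

#' Simulate pre-mapped reads from a template
#'
#' Emits reads with uniformly random start positions on the template (no
#' wrap-around), as reference-strand base strings plus a strand flag.
#' RNA reads carry each overlapped planted edit independently with
#' probability \code{edited_fraction}; DNA reads never carry edits. Both
#' roles carry planted SNP alternate bases with probability
#' \code{snp_alt_fraction} per read. Per-base sequencing errors are i.i.d.
#' substitutions at \code{sequencing_error_rate}. The number of reads is
#' chosen so mean per-position depth equals the configured coverage.
#' Deterministic given \code{config$seed} and \code{role}.
#'
#' @param template template DNA string (e.g. a minicircle).
#' @param truth truth list; \code{planted_edits} (data.frame with 0-based
#'   \code{position} on the template and \code{rna_base}) and
#'   \code{planted_snps} are honoured when present.
#' @param config a \code{simulation_config}.
#' @param role "RNA" or "DNA".
#' @param rname reference name recorded in the reads.
#' @return object of class \code{aligned_reads}: data.frame with
#'   \code{qname}, \code{rname}, \code{start} (0-based), \code{strand}
#'   ("+"/"-"), \code{seq}; attribute \code{read_length}.
#' @export
simulate_reads <- function(template, truth, config, role = c("RNA", "DNA"),
                           rname = "template") {
  role <- match.arg(role)
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, if (role == "RNA") 4L else 5L))
  assert_dna(template, "template")
  L <- nchar(template)
  rl <- config$read_length_nt
  if (rl > L) stop("read_length exceeds template length")
  coverage <- if (role == "RNA") config$rna_coverage else config$dna_coverage
  if (coverage <= 0) stop("coverage must be positive")
  n_reads <- as.integer(round(coverage * L / rl))
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L  # 0-based
  strands <- ifelse(stats::runif(n_reads) < config$strand_mix, "+", "-")
  tchars <- seq_chars(template)
  # observation-level positions: n_reads x rl, template position per base
  obs_pos <- rep(starts, each = rl) + rep.int(0:(rl - 1L), n_reads)  # 0-based
  bases <- tchars[obs_pos + 1L]
  read_of_obs <- rep(seq_len(n_reads), each = rl)
  # planted SNPs: carried by a snp_alt_fraction share of molecules, any role
  snps <- truth$planted_snps
  if (!is.null(snps) && nrow(snps)) {
    m <- match(obs_pos, snps$position)
    hit <- which(!is.na(m))
    if (length(hit)) {
      carry <- stats::runif(length(hit)) < config$snp_alt_fraction
      bases[hit[carry]] <- snps$alt_base[m[hit[carry]]]
    }
  }
  # planted edits: RNA molecules only, Bernoulli(edited_fraction) per read
  edits <- truth$planted_edits
  if (role == "RNA" && !is.null(edits) && nrow(edits)) {
    m <- match(obs_pos, edits$position)
    hit <- which(!is.na(m))
    if (length(hit)) {
      carry <- stats::runif(length(hit)) < config$edited_fraction
      bases[hit[carry]] <- edits$rna_base[m[hit[carry]]]
    }
  }
  # i.i.d. sequencing errors
  if (config$sequencing_error_rate > 0) {
    n_err <- stats::rbinom(1L, length(bases), config$sequencing_error_rate)
    if (n_err > 0) {
      idx <- sample.int(length(bases), n_err)
      shift <- sample.int(3L, n_err, replace = TRUE)
      cur <- match(bases[idx], DNA_BASES)
      bases[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  m <- matrix(bases, nrow = rl)
  seqs <- do.call(paste0, lapply(seq_len(rl), function(j) m[j, ]))
  reads <- data.frame(
    qname = sprintf("%s_%s_%06d", tolower(role), config$seed,
                    seq_len(n_reads)),
    rname = rname,
    start = starts,
    strand = strands,
    seq = seqs,
    stringsAsFactors = FALSE)
  structure(reads, class = c("aligned_reads", "data.frame"),
            read_length = rl, role = role)
}

#' End-to-end simulation of one minicircle
#'
#' Convenience wrapper: builds a minicircle, plants edits (translated to
#' minicircle coordinates) and SNPs, and simulates RNA and DNA reads.
#'
#' @param config a \code{simulation_config}.
#' @return list: \code{seq}, \code{gene}, \code{truth} (with
#'   \code{planted_edits}, \code{planted_snps} in minicircle coordinates and
#'   \code{edits_gene} in gene coordinates), \code{transcript},
#'   \code{rna_reads}, \code{dna_reads}.
#' @export
simulate_minicircle_experiment <- function(config) {
  mc <- make_minicircle(config)
  pe <- plant_edits(mc$gene, config)
  cds_start <- mc$truth$cds_span[1]
  edits_mc <- pe$edits
  edits_mc$position <- edits_mc$position + cds_start
  mc$truth$planted_edits <- edits_mc
  mc$truth$edits_gene <- pe$edits
  mc$truth$planted_snps <- plant_snps(mc$seq, config,
                                      exclude = edits_mc$position)
  rna <- simulate_reads(mc$seq, mc$truth, config, "RNA",
                        rname = mc$gene$gene_id)
  dna <- simulate_reads(mc$seq, mc$truth, config, "DNA",
                        rname = mc$gene$gene_id)
  c(mc, list(transcript = pe$transcript, rna_reads = rna, dna_reads = dna))
}

#' Packaged per-gene editing count table
#'
#' Returns the packaged 14-row reference table of editing counts in the 14
#' plastid-encoded minicircle genes: CDS length, total edit count, per-type
#' counts for the nine observed editing types, amino-acid substitution count,
#' protein length, and gDNA/cDNA percent identity to Heterocapsa triquetra
#' homologs. For the 16S rRNA row the published per-type digits are
#' internally inconsistent with the row total; the fixture stores the row
#' total and NA per-type counts there (see the packaged TSV header).
#'
#' @return data.frame, one row per gene, with columns \code{gene},
#'   \code{molecule_class}, \code{minicircle_kb}, \code{cds_length_nt},
#'   \code{n_edits}, nine type-count columns named by label ("A/G", ...),
#'   \code{n_aa_substitutions}, \code{protein_length_aa},
#'   \code{identity_pre_pct}, \code{identity_post_pct},
#'   \code{start_override}.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "plastid_editing_counts.tsv",
                      package = "minied")
  if (path == "")
    stop("packaged fixture not found; is the package installed?")
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  so <- as.character(df$start_override)
  so[!is.na(so) & so == ""] <- NA_character_
  df$start_override <- so
  df
}
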