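# Per-gene RNA editing counts for the 14 plastid-encoded minicircle genes of
# Symbiodinium minutum (reference count table packaged for reproducible
# summary statistics).
# Columns: gene; molecule_class; minicircle_kb (estimated minicircle size);
# cds_length_nt (CDS length, nt, excluding the terminal stop); n_edits
# (edits in the coding sequence); nine per-type counts labelled DNA/RNA in U
# notation; n_aa_substitutions (edited sites whose codon translation
# changes); protein_length_aa; n_stop_restorations (premature stop codons
# converted to sense codons by editing); identity_pre_pct / identity_post_pct
# (percent amino-acid identity of the unedited / edited conceptual
# translation to the Heterocapsa triquetra homolog); start_override
# (alternative start codon, DNA alphabet).
# FLAG: for 16S_rRNA the published per-type digits (17,0,1,5,...) sum to 23,
# inconsistent with the published row total of 22; per-type counts are
# stored as NA there and only the row total (22) is kept. rRNA rows carry no
# codon-level fields.
gene	molecule_class	minicircle_kb	cds_length_nt	n_edits	A/G	G/A	C/U	U/C	G/C	G/U	U/G	A/C	A/U	n_aa_substitutions	protein_length_aa	n_stop_restorations	identity_pre_pct	identity_post_pct	start_override
psbA	protein_coding	2.4	1029	4	2	1	0	0	1	0	0	0	0	3	343	0	86	86
psbB	protein_coding	2.5	1500	30	18	3	4	5	0	0	0	0	0	28	500	0	68	72
psbC	protein_coding	2.5	1359	25	15	0	4	2	3	0	0	1	0	22	453	0	73	76
psbD	protein_coding	2.25	1074	8	3	0	0	3	1	0	1	0	0	7	358	0	88	88
psbE	protein_coding	1.8	234	9	4	0	1	0	2	1	0	1	0	8	78	0	67	71
psbI	protein_coding	2.13	108	3	0	0	1	1	0	1	0	0	0	3	36	0	45	45	TTG
petB	protein_coding	2.3	657	23	5	1	2	6	9	0	0	0	0	22	219	1	67	72
petD	protein_coding	2.2	477	33	12	4	2	6	8	0	0	1	0	28	159	1	51	54	ATA
psaA	protein_coding	3.3	2022	100	52	8	20	13	2	0	0	5	0	84	674	0	56	60
psaB	protein_coding	3.2	2103	85	53	5	15	6	4	0	0	1	1	78	701	0	54	57	TTT
atpA	protein_coding	2.4	1434	43	28	3	5	6	1	0	0	0	0	37	478	0	67	70
atpB	protein_coding	3.0	1971	50	29	3	5	10	2	0	0	1	0	44	657	0	51	53
16S_rRNA	rRNA	2.35	794	22	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
23S_rRNA	rRNA	2.5	1138	36	26	0	7	0	1	2	0	0	0	NA	NA	NA	NA	NA
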