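# The planted-truth generator: determinism, leakage control, and moment
# checks against closed-form Poisson/NB expectations.

# Exhaustive independent scanner: every position where `site` (a plain
# string) occurs in `seq`, allowing self-overlap. Used as the oracle for
# the no-leakage property.
naive_occurrences <- function(seq, site) {
  k <- nchar(site)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    if (substr(seq, i, i + k - 1) == site) hits <- c(hits, i)
  }
  hits
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(scr_gain = 0.5), "scr_gain")
  expect_error(sim_config(ko_loss = 1.5), "ko_loss")
  expect_error(sim_config(utr_len_range = c(20, 50)), "utr_len_range")
  expect_error(sim_config(n_target_genes = 50, n_mrna = 10), "n_target_genes")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
})

test_that("feature counts are forced by the configuration", {
  cfg <- sim_config(n_mrna = 5, n_lncrna = 2, n_target_genes = 3,
                    n_families = 1, seed = 1)
  tx <- generate_transcriptome(cfg)
  expect_equal(sum(tx$annotations$feature_class == "three_prime_UTR"), 5L)
  expect_equal(sum(tx$annotations$feature_class == "lncRNA"), 2L)
  expect_length(tx$truth$target_gene_ids, 3L)
  # every planted site sits inside its host UTR or the sponge lncRNA
  host <- tx$annotations[match(tx$truth$sites$utr_id, tx$annotations$name), ]
  expect_true(all(tx$truth$sites$start >= host$start &
                    tx$truth$sites$end <= host$end))
})

test_that("the generator is a pure function of (config, seed)", {
  cfg <- small_sim(3)
  expect_identical(generate_transcriptome(cfg), generate_transcriptome(cfg))
  tx <- generate_transcriptome(cfg)
  expect_identical(generate_clip_reads(tx, "WT"), generate_clip_reads(tx, "WT"))
  expect_identical(generate_counts(tx), generate_counts(tx))
  expect_error(generate_clip_reads(tx, "het"), "unknown genotype")
})

test_that("no non-target sequence carries a canonical site of any family (exhaustive scan)", {
  cfg <- small_sim(9)
  tx <- generate_transcriptome(cfg)
  fams <- tx$families
  sites <- tx$truth$sites
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]), collapse = "")
  }
  for (nm in names(tx$sequences)) {
    seq <- tx$sequences[[nm]]
    for (i in seq_len(nrow(fams))) {
      core <- rc(substr(fams$seed7[i], 1, 6))
      hits <- naive_occurrences(seq, core)
      planted <- sites[sites$utr_id == nm & sites$family_id == fams$family_id[i], ]
      host <- tx$annotations[tx$annotations$name == nm, ]
      expected <- (planted$start - host$start) + 2L  # core starts inside the 8-mer
      expect_setequal(hits, expected)
    }
  }
})

test_that("site read means follow the genotype rules of the planted circuit", {
  cfg <- sim_config(n_mrna = 210, n_lncrna = 2, n_target_genes = 200,
                    n_families = 1, background_rate = 0,
                    sponge_site_strength = 0, site_enrichment_wt = 10, seed = 7)
  tx <- generate_transcriptome(cfg)
  # Poisson sum oracle: 200 sites x mean 10 -> total within +/- 3 sd of 2000
  wt <- generate_clip_reads(tx, "WT")
  expect_lt(abs(wt$total_reads - 2000), 3 * sqrt(2000))
  # ko_loss = 0: no site-derived reads at focal sites at all
  ko <- generate_clip_reads(tx, "ko")
  expect_equal(ko$total_reads, 0L)
  # scr genotype: sponge site mean is zero, mRNA sites gain scr_gain
  cfg2 <- sim_config(n_mrna = 40, n_lncrna = 2, n_target_genes = 10,
                     n_families = 1, scr_gain = 2, seed = 7)
  tx2 <- generate_transcriptome(cfg2)
  exp_tab <- tx2$truth$site_expected
  sponge_site <- tx2$truth$sites$gene_id == tx2$truth$sponge_id
  expect_equal(exp_tab$scr[sponge_site], 0)
  expect_equal(exp_tab$WT[sponge_site], cfg2$sponge_site_strength)
  expect_equal(exp_tab$scr[!sponge_site], exp_tab$WT[!sponge_site] * 2)
  expect_equal(exp_tab$ko[!sponge_site], exp_tab$WT[!sponge_site] * 0)
})

test_that("raising scr_gain strictly increases planted scr site means", {
  tx1 <- generate_transcriptome(small_sim(5, scr_gain = 1.2))
  tx2 <- generate_transcriptome(small_sim(5, scr_gain = 2.5))
  focal <- tx1$truth$sites$family_id == tx1$truth$focal_family &
    tx1$truth$sites$gene_id != tx1$truth$sponge_id
  expect_true(all(tx2$truth$site_expected$scr[focal] >
                    tx1$truth$site_expected$scr[focal]))
})

test_that("count matrices carry the planted expression effects", {
  # zero effects -> zero planted log2FC everywhere
  cfg0 <- small_sim(4, de_effect_scr = 0, de_effect_ko = 0, module_effect = 0)
  sc0 <- generate_counts(generate_transcriptome(cfg0))
  expect_true(all(sc0$truth$planted_lfc$planted_lfc == 0))

  # near-zero dispersion: Poisson limit, per-gene variance ~ mean
  cfg_p <- sim_config(n_mrna = 1000, n_lncrna = 1, n_target_genes = 1,
                      n_families = 1, nb_dispersion = 1e-8, lib_size_sd = 0,
                      n_replicates = 40, seed = 12)
  tx_p <- generate_transcriptome(cfg_p)
  d <- default_design(cfg_p)
  d <- d[d$genotype == "WT" & d$stimulation == "aCD3", ]
  sc_p <- generate_counts(tx_p, design = d)
  m <- rowMeans(sc_p$counts)
  v <- apply(sc_p$counts, 1, var)
  ratio <- v[m > 20] / m[m > 20]
  expect_lt(abs(median(ratio) - 1), 0.15)

  # planted fold change recovered by the estimator within +/- 0.1 (targets
  # are a small fraction of genes so median-of-ratios stays unbiased)
  cfg_e <- sim_config(n_mrna = 1000, n_lncrna = 2, n_target_genes = 60,
                      n_families = 1, de_effect_scr = 0.5, n_replicates = 6,
                      seed = 21)
  tx_e <- generate_transcriptome(cfg_e)
  sc_e <- generate_counts(tx_e)
  s <- sc_e$samples
  use <- s$sample_id[s$stimulation == "aCD3aCD28" & s$genotype %in% c("WT", "scr")]
  cnt <- sc_e$counts[, use]
  sf <- size_factors_median_of_ratios(cnt)
  fc <- gene_log2fc(cnt, sf,
                    s$sample_id[s$genotype == "WT" & s$stimulation == "aCD3aCD28"],
                    s$sample_id[s$genotype == "scr" & s$stimulation == "aCD3aCD28"])
  planted <- fc$gene_id %in% sc_e$truth$target_gene_ids
  expect_lt(abs(mean(fc$log2fc[planted]) - 0.5), 0.1)

  expect_error(generate_counts(tx_e, design = data.frame(
    sample_id = "x", genotype = "mut", stimulation = "aCD3", replicate = 1
  )), "unknown genotype")
})

test_that("write_fixture round-trips through the package readers", {
  cfg <- small_sim(6)
  tx <- generate_transcriptome(cfg)
  reads <- list(WT = generate_clip_reads(tx, "WT"),
                scr = generate_clip_reads(tx, "scr"))
  sc <- generate_counts(tx)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(tx, reads, sc, dir)
  expect_equal(manifest$seed, cfg$seed)

  ann <- read_gff(file.path(dir, "annotations.gff3"))
  orig <- tx$annotations
  ann <- ann[match(orig$name, ann$name), ]
  expect_equal(ann$start, orig$start)
  expect_equal(ann$end, orig$end)
  expect_equal(ann$feature_class, orig$feature_class)

  back <- read_bed(file.path(dir, "reads_WT.bed"))
  expect_equal(back$reads[, c("contig", "start", "end")],
               reads$WT$reads[, c("contig", "start", "end")])

  cnt <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(cnt, sc$counts)
  meta <- read_sample_table(file.path(dir, "samples.tsv"), cnt)
  expect_equal(meta$sample_id, sc$samples$sample_id)

  fa <- read_fasta(file.path(dir, "sequences.fa"))
  expect_identical(fa, tx$sequences)

  # truth gene table: one row per (gene, role); disjoint sets give
  # n_target + module + 1 rows
  roles <- utils::read.delim(file.path(dir, "truth_genes.tsv"))
  expect_equal(nrow(roles),
               1L + length(sc$truth$target_gene_ids) + length(sc$truth$module_gene_ids))
})
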