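# Annotation occupancy integration, ranking, masking, and the ZTNB peak
# caller.

toy_annotations <- function() {
  ann <- intervals("c1", c(0, 200, 400), c(100, 300, 500),
                   name = c("A", "B", "C"), strand = "+")
  ann$feature_class <- "lncRNA"
  ann
}

test_that("annotation totals assign reads to overlapped annotations", {
  ann <- toy_annotations()
  reads <- intervals("c1", c(10, 40, 70, 210, 600), c(40, 70, 100, 240, 630))
  tab <- annotation_read_totals(reads, ann)
  expect_equal(tab$total_reads, c(3L, 1L, 0L))
  expect_equal(tab$annotation_id, c("A", "B", "C"))
  # mask covering all of A removes its reads but not B's
  tab_m <- annotation_read_totals(reads, ann, mask = intervals("c1", 0, 100))
  expect_equal(tab_m$total_reads, c(0L, 1L, 0L))
  expect_equal(tab_m$masked_length, c(100, 0, 0))
})

test_that("annotation totals match the per-read brute-force oracle", {
  set.seed(77)
  for (rep in 1:10) {
    ann <- random_intervals(6)
    ann$feature_class <- "lncRNA"
    reads <- random_intervals(40)
    mask <- random_intervals(3)
    expect_equal(annotation_read_totals(reads, ann)$total_reads,
                 oracle_totals(reads, ann), ignore_attr = TRUE)
    expect_equal(annotation_read_totals(reads, ann, mask)$total_reads,
                 oracle_totals(reads, ann, mask), ignore_attr = TRUE)
  }
})

test_that("masking can only decrease totals (monotonicity)", {
  set.seed(31)
  for (rep in 1:10) {
    ann <- random_intervals(8)
    ann$feature_class <- "three_prime_UTR"
    reads <- random_intervals(60)
    mask <- random_intervals(5)
    expect_true(all(annotation_read_totals(reads, ann, mask)$total_reads <=
                      annotation_read_totals(reads, ann)$total_reads))
  }
})

test_that("ranking is deterministic, a permutation, and percentiles cover nonzero rows", {
  ann <- toy_annotations()
  reads <- intervals("c1", c(10, 40, 70, 210), c(40, 70, 100, 240))
  tab <- annotation_read_totals(reads, ann)
  rk <- rank_by_occupancy(tab, "lncRNA")
  expect_equal(rk$annotation_id, c("A", "B", "C"))
  expect_equal(rk$rank_within_class, 1:3)
  expect_equal(rk$percentile_within_class, c(100, 50, NA))
  expect_error(rank_by_occupancy(tab, "CDS"), "absent")

  # all-equal totals: lexicographic, deterministic, ranks a permutation
  tab$total_reads <- 5L
  rk2 <- rank_by_occupancy(tab, "lncRNA")
  expect_equal(rk2$annotation_id, sort(tab$annotation_id))
  expect_equal(sort(rk2$rank_within_class), seq_len(nrow(rk2)))

  # formula check at scale: rank 1 among 11000 nonzero -> percentile 100
  big <- data.frame(annotation_id = sprintf("x%05d", 1:11000),
                    feature_class = "lncRNA",
                    total_reads = 11000:1, length = 100, masked_length = 0)
  expect_equal(rank_by_occupancy(big, "lncRNA")$percentile_within_class[1], 100)
})

test_that("class median ratio follows its closed form and recovers planted depth", {
  tab <- data.frame(
    annotation_id = letters[1:6],
    feature_class = rep(c("lncRNA", "three_prime_UTR"), each = 3),
    total_reads = c(2, 4, 6, 8, 16, 64), length = 100, masked_length = 0
  )
  expect_equal(class_median_ratio(tab, "lncRNA", "three_prime_UTR"), 4)
  tab$total_reads <- rep(c(2, 4, 6), 2)
  expect_equal(class_median_ratio(tab, "lncRNA", "three_prime_UTR"), 1)
  tab$total_reads[4:6] <- 0
  expect_error(class_median_ratio(tab, "lncRNA", "three_prime_UTR"), "> 0 reads")

  # planted 5x depth difference, matched lengths -> ratio near 5 over 20
  # seeds (long features keep read-boundary edge effects negligible)
  ratios <- vapply(1:20, function(s) {
    cfg <- sim_config(n_mrna = 40, n_lncrna = 25, n_target_genes = 1,
                      n_families = 1, utr_len_range = c(2000, 2000),
                      lnc_len_range = c(2000, 2000), lncrna_depth_factor = 0.2,
                      background_rate = 50, site_enrichment_wt = 0,
                      sponge_site_strength = 0, seed = 1000 + s)
    tx <- generate_transcriptome(cfg)
    tab <- annotation_read_totals(generate_clip_reads(tx, "WT"), tx$annotations)
    class_median_ratio(tab, "lncRNA", "three_prime_UTR")
  }, numeric(1))
  expect_true(all(ratios >= 4 & ratios <= 6))
})

test_that("an isolated high bin among sparse background becomes exactly one peak", {
  set.seed(1)
  cnt <- integer(200)
  cnt[sample(200, 15)] <- 1L   # sparse single-read background bins
  cnt[100] <- 50L
  reads <- reads_from_bins(cnt)
  region <- intervals("c1", 0, 200 * 30, name = "r")
  pk <- call_peaks(reads, region, bin_size = 30, alpha = 0.05)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= 99 * 30 && pk$end >= 100 * 30)
  expect_equal(pk$density, pk$reads_in_peak / (pk$end - pk$start))
})

test_that("adjacent significant bins merge into one peak of twice the bin size", {
  set.seed(2)
  cnt <- integer(300)
  cnt[sample(300, 30)] <- 1L
  cnt[150:151] <- 60L
  reads <- reads_from_bins(cnt)
  region <- intervals("c1", 0, 300 * 30, name = "r")
  pk <- call_peaks(reads, region, bin_size = 30, alpha = 0.05)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$end - pk$start, 60)
})

test_that("too few positive bins is an error", {
  reads <- intervals("c1", c(5, 35), c(35, 65))
  region <- intervals("c1", 0, 3000, name = "r")
  expect_error(call_peaks(reads, region), "too few nonzero bins")
})

test_that("the caller recovers spiked bins on NB background (recall/precision >= 0.9)", {
  set.seed(99)
  nbin <- 2000
  bg <- rnbinom(nbin, size = 2, mu = 2)  # dispersion 0.5
  spike_idx <- sample(nbin, 20)
  cnt <- bg
  cnt[spike_idx] <- cnt[spike_idx] + rpois(20, 40)
  reads <- reads_from_bins(cnt)
  region <- intervals("c1", 0, nbin * 30, name = "r")
  pk <- call_peaks(reads, region, bin_size = 30, alpha = 0.05)
  called <- unlist(lapply(seq_len(nrow(pk)), function(i) {
    seq(pk$start[i] / 30 + 1, pk$end[i] / 30)
  }))
  recall <- mean(spike_idx %in% called)
  precision <- mean(called %in% spike_idx)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("peak density percentiles follow the rank formula", {
  ref <- data.frame(density = c(1, 2, 3))
  q <- data.frame(density = 10)
  out <- peak_density_percentiles(q, ref)
  expect_equal(out$density_rank, 1)
  expect_equal(out$density_percentile, 100)
  out2 <- peak_density_percentiles(data.frame(density = 2), ref)
  expect_equal(out2$density_percentile, 100 * (1 - 1 / 3), tolerance = 1e-12)
  out3 <- peak_density_percentiles(data.frame(density = 0.1), ref)
  expect_lt(out3$density_percentile, 100 / 3)
  expect_error(peak_density_percentiles(q, ref[0, , drop = FALSE]), "empty reference")
})

test_that("site fold changes compare normalized site counts between genotypes", {
  # A: 10 of 100 reads at the site; B: 1 of 100 -> fold change 10
  tx_iv <- intervals("c1", 0, 1000, name = "t")
  site <- intervals("c1", 100, 130, name = "s")
  mk <- function(n_site, n_other) {
    intervals("c1", c(rep(100, n_site), seq(500, 500 + n_other - 1)),
              c(rep(130, n_site), seq(530, 530 + n_other - 1)))
  }
  a <- mk(10, 90); b <- mk(1, 99)
  res <- site_coverage_fold_change(site, a, b, tx_iv)
  expect_equal(res$fold_change, 10)
  expect_false(res$infinite)
  same <- site_coverage_fold_change(site, a, a, tx_iv)
  expect_equal(same$fold_change, 1)
  # zero site reads in B -> flagged infinite sentinel
  res_inf <- site_coverage_fold_change(site, a, mk(0, 100), tx_iv)
  expect_true(res_inf$infinite)
  expect_equal(res_inf$fold_change, Inf)
  empty <- intervals(character(0), numeric(0), numeric(0))
  expect_error(site_coverage_fold_change(site, a, empty, tx_iv), "zero reads")
  expect_error(site_coverage_fold_change(intervals("c2", 0, 10), a, b, tx_iv),
               "contain")
})

test_that("sponge-site binding collapses in the scrambled genotype", {
  cfg <- sim_config(n_mrna = 50, n_lncrna = 3, n_target_genes = 10,
                    n_families = 1, sponge_site_strength = 60,
                    background_rate = 20, seed = 17)
  tx <- generate_transcriptome(cfg)
  wt <- generate_clip_reads(tx, "WT")
  scr <- generate_clip_reads(tx, "scr")
  truth <- tx$truth
  srow <- truth$sites[truth$sites$gene_id == truth$sponge_id, ]
  site <- intervals(srow$contig, srow$start, srow$end, name = srow$site_id)
  lnc <- tx$annotations[tx$annotations$name == truth$sponge_id, ]
  res <- site_coverage_fold_change(site, scr, wt, lnc[, 1:6])
  expect_lt(res$fold_change, 0.2)
})
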