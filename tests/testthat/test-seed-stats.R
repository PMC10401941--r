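# Canonical seed matching, occupancy fractions, and the paired logit test.

fam1516 <- seed_family("miR-15/16", "AGCAGCA")

test_that("seed matching reproduces hand-derived canonical sites", {
  # 8mer: reverse complement of positions 2-8 plus A opposite position 1
  s <- find_seed_sites("AAATGCTGCTAAA", fam1516)
  expect_equal(nrow(s), 1L)
  expect_equal(s$match_type, "8mer")
  expect_equal(c(s$start, s$end), c(3, 11))

  # no complementarity -> empty
  expect_equal(nrow(find_seed_sites("AAAAAAA", fam1516)), 0L)

  # exact 7mer-m8 without the trailing A
  s2 <- find_seed_sites("TGCTGCT", fam1516)
  expect_equal(s2$match_type, "7mer-m8")
  expect_equal(c(s2$start, s2$end), c(0, 7))

  # 7mer-A1: core + A, no match at position 8
  s3 <- find_seed_sites("CCGCTGCTACC", fam1516)
  expect_equal(s3$match_type, "7mer-A1")
  expect_equal(c(s3$start, s3$end), c(2, 9))

  # bare 6mer core
  s4 <- find_seed_sites("CCGCTGCTCC", fam1516)
  expect_equal(s4$match_type, "6mer")
  expect_equal(c(s4$start, s4$end), c(2, 8))

  # U and T are interchangeable on both sides
  expect_equal(find_seed_sites("AAAUGCUGCUAAA", fam1516)$match_type, "8mer")
  expect_error(find_seed_sites("ANNNA", fam1516), "invalid character")
  expect_error(seed_family("x", "AGCAGC"), "exactly 7")
})

test_that("overlapping self-similar cores are all reported", {
  # GCTGCT repeated with period 3: two overlapping core matches
  s <- find_seed_sites("GCTGCTGCT", fam1516)
  expect_equal(nrow(s), 2L)
})

test_that("logit transform is clamped, exact, and monotone", {
  expect_equal(logit_fraction(0.5), 0)
  expect_equal(logit_fraction(0.2), log(0.25), tolerance = 1e-12)
  expect_equal(logit_fraction(1), log(0.999 / 0.001), tolerance = 1e-12)
  expect_equal(logit_fraction(0), -log(0.999 / 0.001), tolerance = 1e-12)
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(logit_fraction(f)) >= 0))
})

# tiny geometry: two UTRs with sites, reads placed by hand
tiny_sites <- function() {
  data.frame(
    site_id = c("s1", "s2"), gene_id = c("g1", "g2"),
    utr_id = c("g1_UTR", "g2_UTR"), family_id = "miR-15/16",
    match_type = "8mer", contig = "c1", start = c(50, 250), end = c(58, 258),
    stringsAsFactors = FALSE
  )
}

tiny_utrs <- function() {
  u <- intervals("c1", c(0, 200), c(100, 300), name = c("g1_UTR", "g2_UTR"))
  u$feature_class <- "three_prime_UTR"
  u
}

test_that("support requires a full-overlap read in every required genotype", {
  sites <- tiny_sites()
  covering <- function(n1, n2) {
    read_set(intervals("c1", c(rep(40, n1), rep(240, n2)),
                       c(rep(70, n1), rep(270, n2))))
  }
  wt <- covering(1, 1)
  scr <- covering(1, 0)
  supp <- supported_sites(sites, list(WT = wt, scr = scr))
  expect_equal(supp$site_id, "s1")
  expect_equal(attr(supp, "n_sites"), 1L)
  both <- supported_sites(sites, list(WT = wt, scr = covering(2, 3)))
  expect_equal(attr(both, "n_sites"), 2L)
  expect_equal(attr(both, "n_distinct_genes"), 2L)
  # a 1-nt grazing overlap does not count as support
  graze <- read_set(intervals("c1", c(21, 240), c(51, 270)))
  supp2 <- supported_sites(sites, list(WT = graze, scr = graze))
  expect_equal(supp2$site_id, "s2")
  expect_error(supported_sites(sites, list(WT = wt)), "scr")
})

test_that("occupancy fractions divide site reads by UTR reads", {
  sites <- tiny_sites()[1, ]
  utrs <- tiny_utrs()
  # 2 reads over the site, 8 elsewhere in the UTR -> fraction 0.2
  rs <- read_set(intervals("c1", c(45, 45, seq(2, 16, by = 2)),
                           c(75, 75, seq(32, 46, by = 2))), genotype = "WT")
  rec <- site_occupancy_fractions(rs, sites, utrs)
  expect_equal(rec$fraction, 0.2)
  expect_equal(rec$site_reads, 2L)
  expect_equal(rec$utr_reads, 10L)
  # all 5 UTR reads at the site -> fraction 1 (logit handled by clamping)
  rs2 <- read_set(intervals("c1", rep(45, 5), rep(75, 5)))
  rec2 <- site_occupancy_fractions(rs2, sites, utrs)
  expect_equal(rec2$fraction, 1)
  expect_equal(rec2$logit_fraction, log(0.999 / 0.001))
  # zero-read UTR flagged undefined
  rs3 <- read_set(intervals("c1", 240, 270))
  rec3 <- site_occupancy_fractions(rs3, sites, utrs)
  expect_false(rec3$defined)
  expect_equal(attr(rec3, "n_undefined"), 1L)
})

test_that("fractions agree with a per-read membership oracle on random instances", {
  set.seed(404)
  utrs <- tiny_utrs()
  sites <- tiny_sites()
  for (rep in 1:20) {
    n <- 60
    s <- sample(0:290, n, replace = TRUE)
    rs <- read_set(intervals("c1", s, s + 30), genotype = "WT")
    rec <- site_occupancy_fractions(rs, sites, utrs)
    for (i in 1:2) {
      site_n <- oracle_count(rs$reads, sites[i, c("contig", "start", "end")],
                             min_overlap = 8)
      utr_row <- utrs[utrs$name == sites$utr_id[i], ]
      utr_n <- oracle_count(rs$reads, utr_row, min_overlap = 1)
      expect_equal(rec$site_reads[i], site_n, ignore_attr = TRUE)
      expect_equal(rec$utr_reads[i], utr_n, ignore_attr = TRUE)
      if (utr_n > 0) expect_equal(rec$fraction[i], site_n / utr_n, ignore_attr = TRUE)
    }
  }
})

test_that("fractions are invariant to read duplication (library-size control)", {
  cfg <- small_sim(8)
  tx <- generate_transcriptome(cfg)
  wt <- generate_clip_reads(tx, "WT")
  utrs <- utrs_of(tx)
  sites <- tx$truth$sites[tx$truth$sites$utr_id %in% utrs$name, ]
  rec1 <- site_occupancy_fractions(wt, sites, utrs)
  doubled <- read_set(rbind(wt$reads, wt$reads), genotype = "WT")
  rec2 <- site_occupancy_fractions(doubled, sites, utrs)
  expect_equal(rec2$fraction, rec1$fraction)
  # disjoint sites within one UTR cannot sum to more than 1
  by_utr <- split(rec1$fraction[rec1$defined], sites$utr_id[rec1$defined])
  expect_true(all(vapply(by_utr, sum, numeric(1)) <= 1 + 1e-12))
})

mk_records <- function(fracs, ids = sprintf("s%d", seq_along(fracs))) {
  data.frame(site_id = ids, genotype = "x", site_reads = 1, utr_reads = 2,
             fraction = fracs, logit_fraction = logit_fraction(fracs),
             defined = TRUE, stringsAsFactors = FALSE)
}

test_that("paired occupancy test matches the textbook paired t", {
  # identical fractions: zero-variance convention, p = 1
  a <- mk_records(c(0.2, 0.3, 0.4))
  same <- paired_occupancy_test(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # logit differences {0.1, 0.2, 0.3}: t = 0.2/(0.1/sqrt(3)), df = 2
  base_logit <- c(-1, 0, 1)
  b <- mk_records(stats::plogis(base_logit + c(0.1, 0.2, 0.3)))
  a2 <- mk_records(stats::plogis(base_logit))
  res <- paired_occupancy_test(a2, b)
  expect_equal(res$t_statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-0.2 / (0.1 / sqrt(3)), 2), tolerance = 1e-9)
  expect_equal(res$mean_fraction_a, mean(a2$fraction))
  expect_equal(res$percent_change,
               100 * (mean(b$fraction) - mean(a2$fraction)) / mean(a2$fraction))

  # uniform nonzero shift: p = 0 by the stated convention
  shift <- mk_records(stats::plogis(base_logit + 0.2))
  expect_equal(paired_occupancy_test(a2, shift)$p_value, 0)

  expect_error(paired_occupancy_test(a, mk_records(c(0.1, 0.2), c("s1", "sX"))),
               "unmatched")
})

test_that("the occupancy shift is recovered for the focal family and absent for controls", {
  cfg <- sim_config(n_mrna = 220, n_lncrna = 3, n_target_genes = 150,
                    n_families = 3, n_control_sites = 60, scr_gain = 1.5,
                    seed = 55)
  tx <- generate_transcriptome(cfg)
  reads <- list(WT = generate_clip_reads(tx, "WT"),
                scr = generate_clip_reads(tx, "scr"),
                ko = generate_clip_reads(tx, "ko"))
  utrs <- utrs_of(tx)
  fams <- lapply(seq_len(nrow(tx$families)), function(i) {
    seed_family(tx$families$family_id[i], tx$families$seed7[i])
  })
  sites_by_family <- split(tx$truth$sites[tx$truth$sites$utr_id %in% utrs$name, ],
                           tx$truth$sites$family_id[tx$truth$sites$utr_id %in% utrs$name])
  screen <- control_family_screen(fams, reads, sites_by_family,
                                  pair = c("WT", "scr"), utrs = utrs)
  focal <- screen$family_id == "miR-15/16"
  expect_true(all(screen$testable))
  expect_lt(screen$padj[focal], 0.05)
  expect_gt(screen$mean_fraction_b[focal], screen$mean_fraction_a[focal])
  expect_true(all(screen$padj[!focal] > 0.05))

  # knockout direction: percent change negative, larger magnitude with less background
  supp <- supported_sites(sites_by_family[["miR-15/16"]], reads)
  f_wt <- site_occupancy_fractions(reads$WT, supp, utrs)
  f_ko <- site_occupancy_fractions(reads$ko, supp, utrs)
  expect_lt(paired_occupancy_test(f_wt, f_ko)$percent_change, 0)

  # untestable flag for a family with no sites
  screen2 <- control_family_screen(
    list(seed_family("empty", "AAACCCG")), reads,
    list(empty = sites_by_family[["miR-15/16"]][0, ]), pair = c("WT", "scr"),
    utrs = utrs
  )
  expect_false(screen2$testable)
})
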