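# Orchestration: run the full analysis chain (CLIP occupancy -> seed-site
# statistic -> expression validation -> circuit report) from one structured
# config, with a single master seed and deterministic, machine-readable
# outputs.

#' Assemble a pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()] or argument list for one) or
#' `inputs` (paths: `reads` named by genotype, `annotations`, `sequences`,
#' `counts`, `samples`) must be given. Stage parameters carry the
#' documented defaults of the individual stage functions.
#'
#' @param simulate A [sim_config()], or a list of arguments for one.
#' @param inputs Named list of input paths (see above).
#' @param bin_size Peak-caller bin size in nt.
#' @param alpha Peak-caller BH-adjusted significance level.
#' @param epsilon Logit clamp for occupancy fractions.
#' @param min_overlap Read/site overlap (nt) defining site support.
#' @param min_mean_cpm Low-expression filter threshold.
#' @param site_peak_slop Maximum distance (nt) between a called peak and a
#'   seed site for the two to be matched; read-start binning shifts peaks
#'   up to one read length upstream of the bound motif (default 30).
#' @param lfc_min,padj_max Thresholds for the costimulation gene set.
#' @param cluster_k Flat clusters to cut from the sample dendrogram.
#' @param seed Master seed; overrides the simulate block's seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            bin_size = 30, alpha = 0.05, epsilon = 1e-3,
                            min_overlap = 8, min_mean_cpm = 2,
                            site_peak_slop = 30,
                            lfc_min = 1.5, padj_max = 0.001,
                            cluster_k = 2, seed = 1) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of 'simulate' or 'inputs' must be supplied")
  }
  if (!is.null(simulate)) {
    if (!inherits(simulate, "sim_config")) {
      simulate <- do.call(sim_config, simulate)
    }
    simulate$seed <- seed
  } else {
    needed <- c("reads", "annotations", "sequences", "counts", "samples")
    missing <- setdiff(needed, names(inputs))
    if (length(missing)) {
      stop(sprintf("pipeline config lacks input field(s): %s",
                   paste(missing, collapse = ", ")))
    }
    paths <- c(unlist(inputs$reads), inputs$annotations, inputs$sequences,
               inputs$counts, inputs$samples)
    absent <- paths[!file.exists(paths)]
    if (length(absent)) {
      stop(sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")))
    }
  }
  structure(list(
    simulate = simulate, inputs = inputs,
    bin_size = bin_size, alpha = alpha, epsilon = epsilon,
    min_overlap = min_overlap, min_mean_cpm = min_mean_cpm,
    site_peak_slop = site_peak_slop,
    lfc_min = lfc_min, padj_max = padj_max, cluster_k = cluster_k,
    seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full ceRNA-circuit pipeline
#'
#' Stages, in order: (1) CLIP occupancy - annotation read totals, lncRNA
#' ranking, class median ratio, peak calling in lncRNAs (per genotype) and
#' 3'UTRs, peak-density percentiles, and genotype-comparative binding at
#' the candidate sponge site; (2) seed statistic - seed-site discovery per
#' family, supported-site filtering, per-3'UTR occupancy fractions, paired
#' logit tests and the multi-family screen; (3) expression - CPM filter,
#' DE contrasts, target-set KS shift tests, concordance classification,
#' threshold gene set and sample clustering. All randomness flows from the
#' config seed; rerunning with the same config produces byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage TSV/BED files and the report
#'   (created if needed); `NULL` to skip writing.
#' @return A list of class `circuit_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # ---- data acquisition ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    txome <- generate_transcriptome(sim)
    reads <- list(
      WT = generate_clip_reads(txome, "WT", sim),
      scr = generate_clip_reads(txome, "scr", sim),
      ko = generate_clip_reads(txome, "ko", sim)
    )
    simc <- generate_counts(txome, config = sim)
    annotations <- txome$annotations
    sequences <- txome$sequences
    counts <- simc$counts
    samples <- simc$samples
    families <- txome$families
  } else {
    annotations <- read_gff(config$inputs$annotations)
    sequences <- read_fasta(config$inputs$sequences)
    reads <- lapply(stats::setNames(nm = names(config$inputs$reads)), function(g) {
      read_bed(config$inputs$reads[[g]], genotype = g)
    })
    counts <- read_counts_tsv(config$inputs$counts)
    samples <- read_sample_table(config$inputs$samples, counts)
    families <- if (!is.null(config$inputs$families)) {
      utils::read.delim(config$inputs$families, stringsAsFactors = FALSE)
    } else {
      default_families()
    }
  }

  utrs <- annotations[annotations$feature_class == "three_prime_UTR", , drop = FALSE]
  lncs <- annotations[annotations$feature_class == "lncRNA", , drop = FALSE]
  fam_objs <- lapply(seq_len(nrow(families)), function(i) {
    seed_family(families$family_id[i], families$seed7[i])
  })
  focal_fam <- fam_objs[[1]]

  # ---- stage 1: CLIP occupancy -------------------------------------------
  totals <- annotation_read_totals(reads$WT, annotations)
  ranked_lnc <- rank_by_occupancy(totals, "lncRNA")
  median_ratio <- class_median_ratio(totals, "lncRNA", "three_prime_UTR")
  candidate_sponge <- ranked_lnc$annotation_id[1]

  peaks <- lapply(reads, function(rs) {
    call_peaks(rs, lncs, bin_size = config$bin_size, alpha = config$alpha)
  })
  utr_peaks <- call_peaks(reads$WT, utrs, bin_size = config$bin_size,
                          alpha = config$alpha)

  # focal-family site inside the candidate sponge, genomic coordinates
  sponge_seq <- sequences[[candidate_sponge]]
  sponge_row <- lncs[lncs$name == candidate_sponge, , drop = FALSE]
  sponge_sites <- find_seed_sites(sponge_seq, focal_fam,
                                  gene_id = candidate_sponge,
                                  utr_id = candidate_sponge)
  sponge_site_fc <- NULL
  sponge_peak_overlap <- NULL
  if (nrow(sponge_sites)) {
    best <- sponge_sites[order(match(sponge_sites$match_type,
                                     c("8mer", "7mer-m8", "7mer-A1", "6mer"))), ][1, ]
    site_iv <- intervals(sponge_row$contig, sponge_row$start + best$start,
                         sponge_row$start + best$end, name = best$site_id)
    sponge_site_fc <- list(
      scr_vs_WT = site_coverage_fold_change(site_iv, reads$scr, reads$WT, sponge_row),
      ko_vs_WT = site_coverage_fold_change(site_iv, reads$ko, reads$WT, sponge_row)
    )
    # read-start binning places a peak up to one read length upstream of the
    # bound motif, so the site/peak match allows that much slop
    slop <- config$site_peak_slop
    near_site <- function(pk) {
      nrow(pk) > 0 & pk$contig == site_iv$contig &
        pk$start < site_iv$end + slop & pk$end > site_iv$start - slop
    }
    sponge_peak_overlap <- vapply(peaks, function(pk) {
      nrow(pk) > 0 && any(near_site(pk))
    }, logical(1))
    # density percentile of the sponge-site peak among UTR peaks (WT)
    wt_pk <- peaks$WT
    hit <- which(near_site(wt_pk))
    sponge_peak_pct <- if (length(hit) && nrow(utr_peaks)) {
      peak_density_percentiles(wt_pk[hit[1], , drop = FALSE], utr_peaks)
    } else {
      NULL
    }
  } else {
    sponge_peak_pct <- NULL
  }

  # ---- stage 2: seed statistic -------------------------------------------
  utr_seqs <- sequences[names(sequences) %in% utrs$name]
  sites_by_family <- lapply(fam_objs, function(f) {
    scan_seed_sites(utr_seqs, f, utrs = utrs)
  })
  names(sites_by_family) <- vapply(fam_objs, `[[`, character(1), "family_id")

  focal_sites <- sites_by_family[[focal_fam$family_id]]
  supp <- supported_sites(focal_sites, reads, required = c("WT", "scr"),
                          min_overlap = config$min_overlap)
  frac <- lapply(reads, function(rs) {
    site_occupancy_fractions(rs, supp, utrs, min_overlap = config$min_overlap)
  })
  test_scr <- paired_occupancy_test(frac$WT, frac$scr, epsilon = config$epsilon)
  test_ko <- paired_occupancy_test(frac$WT, frac$ko, epsilon = config$epsilon)
  screen <- control_family_screen(fam_objs, reads, sites_by_family,
                                  pair = c("WT", "scr"), utrs = utrs,
                                  min_overlap = config$min_overlap)

  # ---- stage 3: expression ------------------------------------------------
  filtered <- cpm_filter(counts, config$min_mean_cpm)
  target_genes <- unique(supp$gene_id)
  de_scr <- de_analysis(filtered, samples, "genotype", "WT", "scr",
                        subset = samples$stimulation == "aCD3aCD28")
  de_ko <- de_analysis(filtered, samples, "genotype", "fl", "ko",
                       subset = samples$stimulation == "aCD3aCD28")
  ks_scr <- ecdf_shift_test(de_scr, target_genes)
  ks_ko <- ecdf_shift_test(de_ko, target_genes)
  venn <- concordance_venn(de_scr, de_ko, target_genes)

  de_costim <- de_analysis(filtered, samples, "stimulation",
                           "aCD3aCD28", "aCD3",
                           subset = samples$genotype == "WT")
  costim_set <- threshold_gene_set(de_costim, config$lfc_min, config$padj_max)
  cluster_res <- NULL
  cluster_samples_used <- samples$sample_id[samples$genotype %in% c("WT", "scr")]
  if (length(costim_set$ids) >= 2L) {
    sf <- size_factors_median_of_ratios(filtered[, cluster_samples_used, drop = FALSE])
    norm <- log2(sweep(filtered[, cluster_samples_used, drop = FALSE], 2, sf, "/") + 0.5)
    cluster_res <- cluster_samples(norm, costim_set, k = config$cluster_k)
  }

  report <- structure(list(
    seed = config$seed,
    config_hash = hash_label(paste(deparse(config), collapse = "")),
    candidate_sponge = candidate_sponge,
    sponge_rank = 1L,
    lncrna_ranking = ranked_lnc,
    median_ratio_utr_over_lncrna = median_ratio,
    n_lnc_peaks = vapply(peaks, nrow, integer(1)),
    sponge_site_fold_change = sponge_site_fc,
    sponge_site_peak_called = sponge_peak_overlap,
    sponge_peak_density_percentile =
      if (!is.null(sponge_peak_pct)) sponge_peak_pct$density_percentile else NA_real_,
    n_supported_sites = attr(supp, "n_sites"),
    n_supported_genes = attr(supp, "n_distinct_genes"),
    occupancy_test_scr = test_scr,
    occupancy_test_ko = test_ko,
    family_screen = screen,
    ks_scr = ks_scr, ks_ko = ks_ko,
    venn = venn,
    n_costim_genes = length(costim_set$ids),
    costim_set = costim_set,
    clustering = cluster_res,
    n_genes_tested = nrow(filtered)
  ), class = "circuit_report")

  if (!is.null(out_dir)) {
    write_report_files(report, list(
      totals = totals, peaks = peaks, utr_peaks = utr_peaks, supp = supp,
      frac = frac, de_scr = de_scr, de_ko = de_ko, de_costim = de_costim,
      samples = samples
    ), out_dir)
  }
  report
}

# Write per-stage tables and the deterministic flat-text report.
write_report_files <- function(report, stage, out_dir) {
  write_tsv_file(stage$totals, file.path(out_dir, "occupancy_totals.tsv"))
  write_tsv_file(report$lncrna_ranking, file.path(out_dir, "lncrna_ranking.tsv"))
  for (g in names(stage$peaks)) {
    pk <- stage$peaks[[g]]
    if (nrow(pk)) {
      write_bed(pk[, c("contig", "start", "end", "name", "score", "strand")],
                file.path(out_dir, sprintf("peaks_lncrna_%s.bed", g)))
    }
    write_tsv_file(pk, file.path(out_dir, sprintf("peaks_lncrna_%s.tsv", g)))
  }
  write_tsv_file(stage$utr_peaks, file.path(out_dir, "peaks_utr_WT.tsv"))
  write_tsv_file(stage$supp, file.path(out_dir, "supported_sites.tsv"))
  for (g in names(stage$frac)) {
    write_tsv_file(stage$frac[[g]], file.path(out_dir, sprintf("fractions_%s.tsv", g)))
  }
  write_tsv_file(report$family_screen, file.path(out_dir, "family_screen.tsv"))
  write_tsv_file(stage$de_scr, file.path(out_dir, "de_WT_vs_scr.tsv"))
  write_tsv_file(stage$de_ko, file.path(out_dir, "de_fl_vs_ko.tsv"))
  write_tsv_file(stage$de_costim, file.path(out_dir, "de_costim_WT.tsv"))
  writeLines(report$costim_set$ids, file.path(out_dir, "costim_gene_set.txt"))
  if (!is.null(report$clustering)) {
    write_tsv_file(
      data.frame(sample_id = names(report$clustering$labels),
                 cluster = unname(report$clustering$labels)),
      file.path(out_dir, "sample_clusters.tsv")
    )
    writeLines(report$clustering$newick, file.path(out_dir, "sample_dendrogram.nwk"))
  }
  writeLines(report_lines(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# Deterministic flat key=value rendering of the report.
report_lines <- function(report) {
  num <- function(x) formatC(x, digits = 10, format = "g")
  kv <- c(
    seed = report$seed,
    config_hash = report$config_hash,
    candidate_sponge = report$candidate_sponge,
    median_ratio_utr_over_lncrna = num(report$median_ratio_utr_over_lncrna),
    sponge_peak_density_percentile = num(report$sponge_peak_density_percentile),
    n_supported_sites = report$n_supported_sites,
    n_supported_genes = report$n_supported_genes,
    occupancy_scr_percent_change = num(report$occupancy_test_scr$percent_change),
    occupancy_scr_p = num(report$occupancy_test_scr$p_value),
    occupancy_ko_percent_change = num(report$occupancy_test_ko$percent_change),
    occupancy_ko_p = num(report$occupancy_test_ko$p_value),
    ks_scr_D = num(report$ks_scr$D), ks_scr_p = num(report$ks_scr$p_value),
    ks_scr_direction = report$ks_scr$direction,
    ks_ko_D = num(report$ks_ko$D), ks_ko_p = num(report$ks_ko$p_value),
    ks_ko_direction = report$ks_ko$direction,
    venn_n_targets = report$venn$n_targets,
    venn_both = report$venn$n_both,
    venn_either = report$venn$n_either,
    venn_pct_either = num(report$venn$pct_either),
    n_costim_genes = report$n_costim_genes,
    n_genes_tested = report$n_genes_tested
  )
  if (!is.null(report$sponge_site_fold_change)) {
    kv <- c(kv,
            sponge_site_fc_scr_vs_WT = num(report$sponge_site_fold_change$scr_vs_WT$fold_change),
            sponge_site_fc_ko_vs_WT = num(report$sponge_site_fold_change$ko_vs_WT$fold_change))
  }
  if (!is.null(report$sponge_site_peak_called)) {
    kv <- c(kv, sponge_site_peak_called_WT = report$sponge_site_peak_called[["WT"]],
            sponge_site_peak_called_ko = report$sponge_site_peak_called[["ko"]])
  }
  paste0(names(kv), "=", unname(kv))
}

#' @export
print.circuit_report <- function(x, ...) {
  cat("ceRNA circuit report\n")
  cat(sprintf("  candidate sponge lncRNA: %s (rank 1 of %d by CLIP reads)\n",
              x$candidate_sponge, nrow(x$lncrna_ranking)))
  cat(sprintf("  median UTR / median lncRNA read totals: %.2f\n",
              x$median_ratio_utr_over_lncrna))
  cat(sprintf("  supported focal sites: %d in %d genes\n",
              x$n_supported_sites, x$n_supported_genes))
  cat("  occupancy shift (scr vs WT): "); print(x$occupancy_test_scr)
  cat("  occupancy shift (ko vs WT):  "); print(x$occupancy_test_ko)
  cat("  target derepression KS (WT vs scr): "); print(x$ks_scr)
  cat("  target derepression KS (fl vs ko):  "); print(x$ks_ko)
  cat("  "); print(x$venn)
  cat(sprintf("  costimulation gene set: %d genes\n", x$n_costim_genes))
  invisible(x)
}
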