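# Synthetic-data generator: a fully specified transcriptome, genotype-
# specific CLIP read sets, and RNA-seq count matrices with planted ceRNA
# circuit effects, so every downstream stage can be checked by parameter
# recovery.
#
# The planted structure mirrors the biology of a sponge circuit: one lncRNA
# ("the sponge") carries a single 8-mer seed site of the focal miRNA family;
# a set of mRNA 3'UTRs carry one focal site each; control families carry
# sites with no genotype effect. Three CLIP genotypes are emulated:
#   WT  - full binding everywhere;
#   scr - a 5-nt scramble of the sponge site: binding lost at the sponge,
#         gained (x scr_gain) at focal mRNA sites;
#   ko  - the focal miRNA family deleted: focal-site binding multiplied by
#         ko_loss (default 0), control families untouched.

# Built-in seed families (focal family first). seed7 = miRNA positions 2-8.
FAMILY_SEEDS <- data.frame(
  family_id = c("miR-15/16", "miR-101", "let-7", "miR-21", "miR-142"),
  seed7 = c("AGCAGCA", "ACAGUAC", "GAGGUAG", "AGCUUAU", "GUAGUGU"),
  stringsAsFactors = FALSE
)

#' Default seed family table
#'
#' The focal family (miR-15/16) followed by four highly expressed control
#' families (miR-101, let-7, miR-21, miR-142).
#'
#' @param n Number of families to return (focal family first), 1..5.
#' @return data.frame with columns family_id, seed7.
#' @export
default_families <- function(n = 5) {
  stopifnot(n >= 1, n <= nrow(FAMILY_SEEDS))
  FAMILY_SEEDS[seq_len(n), , drop = FALSE]
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the generator; see the
#' methods vignette for the rationale behind each value.
#'
#' @param n_mrna Number of mRNA genes.
#' @param n_lncrna Number of lncRNA genes (the first is the sponge).
#' @param utr_len_range Min/max 3'UTR length in nt (min >= 30).
#' @param lnc_len_range Min/max lncRNA length in nt.
#' @param n_target_genes Number of mRNAs carrying a focal-family 8-mer site.
#' @param n_families Number of seed families (focal + controls), 1..5.
#' @param n_control_sites Planted sites per control family.
#' @param sponge_site_strength Expected CLIP reads at the sponge site (WT).
#' @param background_rate Expected background reads per kb of transcript.
#' @param lncrna_depth_factor Multiplier on `background_rate` for lncRNAs
#'   (emulates their lower expression relative to mRNAs).
#' @param site_enrichment_wt Mean extra reads per target seed site in WT.
#' @param scr_gain Multiplicative occupancy gain at focal mRNA sites in the
#'   scrambled genotype (>= 1).
#' @param ko_loss Multiplicative residual at focal sites in the knockout
#'   genotype (in `[0, 1]`).
#' @param de_effect_scr Planted log2FC of target genes, control vs scrambled.
#' @param de_effect_ko Planted log2FC of target genes, knockout vs control.
#' @param module_size Number of planted costimulation-responsive genes.
#' @param module_effect Planted log2FC of module genes under costimulation.
#' @param module_attenuation Named per-genotype multiplier on `module_effect`.
#' @param nb_dispersion Negative-binomial dispersion of RNA-seq counts.
#' @param n_replicates Replicates per genotype x stimulation.
#' @param lib_size_sd Log-normal sd of per-sample library size factors.
#' @param read_len CLIP read length in nt.
#' @param cds_len Fixed CDS length per mRNA in nt.
#' @param seed Master integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 4000, n_lncrna = 20,
                       utr_len_range = c(150, 300),
                       lnc_len_range = c(500, 2000),
                       n_target_genes = 200, n_families = 5,
                       n_control_sites = 100,
                       sponge_site_strength = 50, background_rate = 50,
                       lncrna_depth_factor = 0.1,
                       site_enrichment_wt = 10, scr_gain = 1.5, ko_loss = 0,
                       de_effect_scr = 0.5, de_effect_ko = 0.5,
                       module_size = 164, module_effect = 2,
                       module_attenuation = c(WT = 1, scr = 1, fl = 1, ko = 1),
                       nb_dispersion = 0.05, n_replicates = 6,
                       lib_size_sd = 0.2,
                       read_len = 30, cds_len = 300, seed = 1) {
  cfg <- list(
    n_mrna = n_mrna, n_lncrna = n_lncrna,
    utr_len_range = utr_len_range, lnc_len_range = lnc_len_range,
    n_target_genes = n_target_genes, n_families = n_families,
    n_control_sites = n_control_sites,
    sponge_site_strength = sponge_site_strength,
    background_rate = background_rate,
    lncrna_depth_factor = lncrna_depth_factor,
    site_enrichment_wt = site_enrichment_wt,
    scr_gain = scr_gain, ko_loss = ko_loss,
    de_effect_scr = de_effect_scr, de_effect_ko = de_effect_ko,
    module_size = module_size, module_effect = module_effect,
    module_attenuation = module_attenuation,
    nb_dispersion = nb_dispersion, n_replicates = n_replicates,
    lib_size_sd = lib_size_sd,
    read_len = read_len, cds_len = cds_len, seed = seed
  )
  counts <- c("n_mrna", "n_lncrna", "n_target_genes", "n_families",
              "module_size", "n_replicates")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(sprintf("sim_config: %s must be >= 1", f))
  }
  if (cfg$scr_gain < 1) stop("sim_config: scr_gain must be >= 1")
  if (cfg$ko_loss < 0 || cfg$ko_loss > 1) stop("sim_config: ko_loss must be in [0,1]")
  if (cfg$utr_len_range[1] < 30) stop("sim_config: utr_len_range min must be >= 30 nt")
  if (cfg$background_rate < 0) stop("sim_config: background_rate must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("sim_config: nb_dispersion must be > 0")
  if (cfg$n_target_genes > cfg$n_mrna) stop("sim_config: n_target_genes > n_mrna")
  if (cfg$n_families > nrow(FAMILY_SEEDS)) {
    stop(sprintf("sim_config: at most %d families are defined", nrow(FAMILY_SEEDS)))
  }
  structure(cfg, class = "sim_config")
}

# --- sequence construction -------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All positions (1-based) at which any family's canonical match core occurs.
# Lookahead matching so that self-overlapping occurrences are all found.
core_matches <- function(seq, cores) {
  hits <- integer(0)
  for (core in cores) {
    m <- gregexpr(paste0("(?=", core, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1L) hits <- c(hits, as.integer(m))
  }
  sort(unique(hits))
}

# Remove every canonical core match by point mutation, except cores whose
# start is listed in `protect_starts` (planted sites); mutations never touch
# positions inside `protect_windows` (1-based start/end matrix covering the
# planted 8-mers). Mutating the 6-mer core destroys all four canonical match
# classes at that locus. Rescans until clean.
scrub_sequence <- function(seq, cores, protect_starts = integer(0),
                           protect_windows = NULL, max_iter = 50) {
  core_len <- 6L
  protected_pos <- if (is.null(protect_windows)) integer(0) else {
    unlist(lapply(seq_len(nrow(protect_windows)),
                  function(i) protect_windows[i, 1]:protect_windows[i, 2]))
  }
  for (iter in seq_len(max_iter)) {
    starts <- core_matches(seq, cores)
    starts <- starts[!starts %in% protect_starts]
    if (length(starts) == 0L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (s in starts) {
      cand <- setdiff(s:(s + core_len - 1L), protected_pos)
      if (length(cand) == 0L) next  # fully inside a planted window; cannot occur
      pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
  stop("scrub_sequence: could not remove spurious seed matches")
}

# 8-mer site string for a family: complement of position 8, then the
# reverse complement of positions 2-7, then A opposite position 1.
family_site8 <- function(seed7) {
  seed_dna <- as_dna(seed7, "seed7")
  paste0(comp_dna(substr(seed_dna, 7, 7)),
         revcomp_dna(substr(seed_dna, 1, 6)), "A")
}

# 6-mer canonical core (reverse complement of positions 2-7).
family_core6 <- function(seed7) {
  revcomp_dna(substr(as_dna(seed7, "seed7"), 1, 6))
}

#' Generate a synthetic transcriptome with planted seed sites
#'
#' Lays out `n_mrna` mRNAs (fixed-length CDS plus a 3'UTR) and `n_lncrna`
#' lncRNAs non-overlapping on one synthetic contig. Exactly one lncRNA (the
#' sponge) carries a focal-family 8-mer site; `n_target_genes` 3'UTRs carry
#' one focal 8-mer each; each control family receives `n_control_sites`
#' 8-mer sites in random 3'UTRs. All remaining sequence is rejection-scrubbed
#' so that it contains no canonical (6-mer or better) match for any
#' configured family. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_transcriptome` with elements
#'   `annotations` (annotation data.frame: gene, CDS, three_prime_UTR,
#'   lncRNA features), `sequences` (named character: UTR and lncRNA
#'   sequences), `transcripts` (interval data.frame of full transcript
#'   spans), `truth` (a `synthetic_truth` list: sponge_id, focal_family,
#'   target_gene_ids, sites table, per-site expected reads by genotype),
#'   and `families` (the seed family table used).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- default_families(config$n_families)
  cores <- vapply(fams$seed7, family_core6, character(1))
  focal <- fams$family_id[1]
  with_seed(derive_seed(config$seed, "transcriptome"), {
    n_m <- config$n_mrna; n_l <- config$n_lncrna
    resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
    utr_len <- resample(seq(config$utr_len_range[1], config$utr_len_range[2]), n_m)
    lnc_len <- resample(seq(config$lnc_len_range[1], config$lnc_len_range[2]), n_l)
    gene_ids <- sprintf("gene%04d", seq_len(n_m))
    lnc_ids <- sprintf("lnc%03d", seq_len(n_l))
    target_ids <- sort(sample(gene_ids, config$n_target_genes))

    # choose site offsets (0-based within UTR / lncRNA); one focal site per
    # target UTR, one focal site in the sponge, control sites scattered.
    site_rows <- list()
    occupied <- lapply(stats::setNames(vector("list", n_m), gene_ids), function(x) integer(0))
    place_site <- function(host_len, taken) {
      # 8-nt windows kept >= 6 nt apart so a spurious 6-mer core can never
      # lie entirely inside protected positions; 0-based offset
      cand <- setdiff(seq(0L, host_len - 8L), unlist(lapply(taken, function(t) (t - 13L):(t + 13L))))
      if (length(cand) == 0L) return(NA_integer_)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    for (g in target_ids) {
      len <- utr_len[match(g, gene_ids)]
      off <- place_site(len, occupied[[g]])
      if (is.na(off)) stop(sprintf("UTR of %s too short for requested sites", g))
      occupied[[g]] <- c(occupied[[g]], off)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        gene_id = g, family_id = focal, offset = off, host = "utr",
        stringsAsFactors = FALSE
      )
    }
    # control sites live in non-target UTRs: a control site sharing a UTR
    # with a focal site would inherit a genotype effect through the shared
    # per-UTR denominator, contaminating the control null
    non_target <- setdiff(gene_ids, target_ids)
    if (config$n_families > 1) {
      if (length(non_target) == 0L) {
        stop("no non-target genes left to host control-family sites")
      }
      for (fi in seq(2, config$n_families)) {
        hosts <- sample(non_target, min(config$n_control_sites, length(non_target)))
        for (g in hosts) {
          len <- utr_len[match(g, gene_ids)]
          off <- place_site(len, occupied[[g]])
          if (is.na(off)) next  # crowded UTR: skip rather than error for controls
          occupied[[g]] <- c(occupied[[g]], off)
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            gene_id = g, family_id = fams$family_id[fi], offset = off, host = "utr",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    sponge_id <- lnc_ids[1]
    sponge_off <- floor(lnc_len[1] / 2)
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      gene_id = sponge_id, family_id = focal, offset = sponge_off, host = "lnc",
      stringsAsFactors = FALSE
    )
    sites <- do.call(rbind, site_rows)

    # build sequences: scrub background, then plant 8-mers, then re-scrub
    # around the planted windows.
    seqs <- character(0)
    build_seq <- function(id, len) {
      s <- scrub_sequence(random_dna(len), cores)
      here <- sites[sites$gene_id == id, , drop = FALSE]
      if (nrow(here)) {
        for (i in seq_len(nrow(here))) {
          s8 <- family_site8(fams$seed7[match(here$family_id[i], fams$family_id)])
          substr(s, here$offset[i] + 1L, here$offset[i] + 8L) <- s8
        }
        # planted cores start one base after the planted 8-mer start
        s <- scrub_sequence(s, cores, protect_starts = here$offset + 2L,
                            protect_windows = cbind(here$offset + 1L, here$offset + 8L))
      }
      s
    }
    for (i in seq_len(n_m)) seqs[paste0(gene_ids[i], "_UTR")] <- build_seq(gene_ids[i], utr_len[i])
    for (i in seq_len(n_l)) seqs[lnc_ids[i]] <- build_seq(lnc_ids[i], lnc_len[i])

    # genomic layout: sequential on one contig with 100-nt gaps
    contig <- "synchr1"
    gap <- 100L
    cursor <- 0L
    ann <- list(); tx <- list()
    for (i in seq_len(n_m)) {
      g <- gene_ids[i]
      s <- cursor
      cds_e <- s + config$cds_len
      utr_e <- cds_e + utr_len[i]
      ann[[length(ann) + 1L]] <- data.frame(
        contig = contig, start = c(s, s, cds_e), end = c(utr_e, cds_e, utr_e),
        name = c(g, paste0(g, "_CDS"), paste0(g, "_UTR")),
        score = 0, strand = "+",
        feature_class = c("other", "CDS", "three_prime_UTR"),
        gene_id = c(NA, g, g), stringsAsFactors = FALSE
      )
      tx[[length(tx) + 1L]] <- data.frame(
        contig = contig, start = s, end = utr_e, name = g, score = 0,
        strand = "+", kind = "mRNA", stringsAsFactors = FALSE
      )
      cursor <- utr_e + gap
    }
    for (i in seq_len(n_l)) {
      l <- lnc_ids[i]
      s <- cursor; e <- s + lnc_len[i]
      ann[[length(ann) + 1L]] <- data.frame(
        contig = contig, start = s, end = e, name = l, score = 0, strand = "+",
        feature_class = "lncRNA", gene_id = NA, stringsAsFactors = FALSE
      )
      tx[[length(tx) + 1L]] <- data.frame(
        contig = contig, start = s, end = e, name = l, score = 0,
        strand = "+", kind = "lncRNA", stringsAsFactors = FALSE
      )
      cursor <- e + gap
    }
    annotations <- do.call(rbind, ann)
    transcripts <- do.call(rbind, tx)
    rownames(annotations) <- rownames(transcripts) <- NULL

    # genomic site coordinates
    utr_rows <- annotations[annotations$feature_class == "three_prime_UTR", ]
    lnc_rows <- annotations[annotations$feature_class == "lncRNA", ]
    host_start <- ifelse(
      sites$host == "utr",
      utr_rows$start[match(paste0(sites$gene_id, "_UTR"), utr_rows$name)],
      lnc_rows$start[match(sites$gene_id, lnc_rows$name)]
    )
    sites_tab <- data.frame(
      site_id = sprintf("site_%s_%s_%d", sites$gene_id,
                        gsub("[^A-Za-z0-9]", "", sites$family_id), sites$offset),
      gene_id = sites$gene_id,
      utr_id = ifelse(sites$host == "utr", paste0(sites$gene_id, "_UTR"), sites$gene_id),
      family_id = sites$family_id,
      match_type = "8mer",
      contig = contig,
      start = host_start + sites$offset,
      end = host_start + sites$offset + 8L,
      strand = "+",
      stringsAsFactors = FALSE
    )

    truth <- structure(list(
      sponge_id = sponge_id,
      focal_family = focal,
      target_gene_ids = target_ids,
      module_gene_ids = character(0),
      sites = sites_tab,
      site_expected = site_expected_reads(sites_tab, sponge_id, focal, config),
      planted_lfc = NULL
    ), class = "synthetic_truth")

    structure(list(
      annotations = annotations, sequences = seqs, transcripts = transcripts,
      truth = truth, families = fams, config = config
    ), class = "sim_transcriptome")
  })
}

# Expected site-derived CLIP reads per (site, genotype).
site_expected_reads <- function(sites_tab, sponge_id, focal, config) {
  is_focal <- sites_tab$family_id == focal
  is_sponge <- sites_tab$gene_id == sponge_id
  wt <- ifelse(is_sponge, config$sponge_site_strength, config$site_enrichment_wt)
  scr <- wt
  scr[is_focal & is_sponge] <- 0
  scr[is_focal & !is_sponge] <- wt[is_focal & !is_sponge] * config$scr_gain
  ko <- wt
  ko[is_focal] <- wt[is_focal] * config$ko_loss
  data.frame(site_id = sites_tab$site_id, WT = wt, scr = scr, ko = ko,
             stringsAsFactors = FALSE)
}

#' Generate a genotype-specific CLIP read set
#'
#' Background reads are Poisson at `background_rate` per kb, uniform over
#' each transcript (lncRNAs attenuated by `lncrna_depth_factor`). Site reads
#' are Poisson with the planted per-genotype mean, with read starts uniform
#' over `[site_start - read_len + 8, site_start]` so every site read covers
#' the full 8-mer. Deterministic given `config$seed` and `genotype` (each
#' genotype has its own derived RNG stream).
#'
#' @param txome A `sim_transcriptome` from [generate_transcriptome()].
#' @param genotype One of `"WT"`, `"scr"`, `"ko"`.
#' @param config The [sim_config()] used to build `txome` (defaults to the
#'   one stored in it).
#' @return A [read_set()].
#' @export
generate_clip_reads <- function(txome, genotype, config = txome$config) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  if (!genotype %in% c("WT", "scr", "ko")) {
    stop(sprintf("unknown genotype '%s' (expected WT, scr or ko)", genotype))
  }
  truth <- txome$truth
  with_seed(derive_seed(config$seed, paste0("clip_", genotype)), {
    tx <- txome$transcripts
    rate <- config$background_rate / 1000 * (tx$end - tx$start) *
      ifelse(tx$kind == "lncRNA", config$lncrna_depth_factor, 1)
    n_bg <- stats::rpois(nrow(tx), rate)
    rl <- config$read_len
    i_bg <- rep.int(seq_len(nrow(tx)), n_bg)
    lo <- tx$start[i_bg]
    hi <- pmax(lo, tx$end[i_bg] - rl)
    s_bg <- lo + floor(stats::runif(length(i_bg)) * (hi - lo + 1))
    mu <- truth$site_expected[[genotype]]
    n_site <- stats::rpois(length(mu), mu)
    i_st <- rep.int(seq_len(nrow(truth$sites)), n_site)
    lo <- truth$sites$start[i_st] - rl + 8L
    hi <- truth$sites$start[i_st]
    s_st <- lo + floor(stats::runif(length(i_st)) * (hi - lo + 1))
    contig <- c(tx$contig[i_bg], truth$sites$contig[i_st])
    start <- c(s_bg, s_st)
    o <- order(start)
    df <- intervals(contig[o], start[o], start[o] + rl,
                    name = if (length(o)) sprintf("read_%s_%06d", genotype, seq_along(o)) else character(0),
                    score = 1, strand = "+")
    read_set(df, library_id = paste0("AHC_", genotype), genotype = genotype)
  })
}

#' Default RNA-seq sample design
#'
#' Genotypes WT, scr (sponge-site scramble), fl (floxed control) and ko
#' (family knockout), each under aCD3 and aCD3aCD28 stimulation with
#' `n_replicates` replicates.
#'
#' @param config A [sim_config()].
#' @return data.frame with sample_id, genotype, stimulation, replicate.
#' @export
default_design <- function(config) {
  g <- c("WT", "scr", "fl", "ko")
  s <- c("aCD3", "aCD3aCD28")
  d <- expand.grid(replicate = seq_len(config$n_replicates),
                   stimulation = s, genotype = g,
                   stringsAsFactors = FALSE)
  d <- d[, c("genotype", "stimulation", "replicate")]
  d$sample_id <- sprintf("%s_%s_r%d", d$genotype, d$stimulation, d$replicate)
  d[, c("sample_id", "genotype", "stimulation", "replicate")]
}

#' Generate an RNA-seq count matrix with planted effects
#'
#' Negative-binomial counts with log-normal gene base means. Target genes'
#' means are multiplied by `2^(-de_effect_scr)` in scr samples and
#' `2^(+de_effect_ko)` in ko samples; module genes' means are multiplied by
#' `2^(module_effect x attenuation[genotype])` under aCD3aCD28 stimulation.
#' Per-sample library size factors are log-normal. Deterministic given
#' `config$seed`.
#'
#' @param txome A `sim_transcriptome`.
#' @param design Sample table (default [default_design()]).
#' @param config The [sim_config()] (defaults to the one in `txome`).
#' @return A list of class `sim_counts`: `counts` (integer matrix),
#'   `samples` (the design) and `truth` (the input truth augmented with
#'   `module_gene_ids` and a `planted_lfc` table per contrast).
#' @export
generate_counts <- function(txome, design = NULL, config = txome$config) {
  stopifnot(inherits(txome, "sim_transcriptome"))
  if (is.null(design)) design <- default_design(config)
  if (!all(design$genotype %in% c("WT", "scr", "fl", "ko"))) {
    stop(sprintf("unknown genotype label(s): %s",
                 paste(setdiff(unique(design$genotype), c("WT", "scr", "fl", "ko")),
                       collapse = ", ")))
  }
  if (!all(design$stimulation %in% c("aCD3", "aCD3aCD28"))) {
    stop(sprintf("unknown stimulation label(s): %s",
                 paste(setdiff(unique(design$stimulation), c("aCD3", "aCD3aCD28")),
                       collapse = ", ")))
  }
  truth <- txome$truth
  with_seed(derive_seed(config$seed, "counts"), {
    mrna <- txome$transcripts$name[txome$transcripts$kind == "mRNA"]
    lnc <- txome$transcripts$name[txome$transcripts$kind == "lncRNA"]
    genes <- c(mrna, lnc)
    base_mu <- stats::rlnorm(length(genes), meanlog = log(100), sdlog = 1)
    names(base_mu) <- genes
    base_mu[truth$sponge_id] <- base_mu[truth$sponge_id] * 20  # sponge is highly expressed
    module <- sort(sample(mrna, min(config$module_size, length(mrna))))

    att <- config$module_attenuation
    n_s <- nrow(design)
    lib <- stats::rlnorm(n_s, 0, config$lib_size_sd)
    mu <- matrix(base_mu, nrow = length(genes), ncol = n_s,
                 dimnames = list(genes, design$sample_id))
    is_target <- genes %in% truth$target_gene_ids
    is_module <- genes %in% module
    for (j in seq_len(n_s)) {
      g <- design$genotype[j]
      mult <- rep(1, length(genes))
      if (g == "scr") mult[is_target] <- mult[is_target] * 2^(-config$de_effect_scr)
      if (g == "ko") mult[is_target] <- mult[is_target] * 2^(config$de_effect_ko)
      if (design$stimulation[j] == "aCD3aCD28") {
        a <- if (!is.null(att) && g %in% names(att)) att[[g]] else 1
        mult[is_module] <- mult[is_module] * 2^(config$module_effect * a)
      }
      mu[, j] <- mu[, j] * mult * lib[j]
    }
    counts <- matrix(
      stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = as.vector(mu)),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
    storage.mode(counts) <- "integer"

    lfc <- rbind(
      data.frame(gene_id = genes, contrast = "WT_vs_scr",
                 planted_lfc = ifelse(is_target, config$de_effect_scr, 0)),
      data.frame(gene_id = genes, contrast = "fl_vs_ko",
                 planted_lfc = ifelse(is_target, -config$de_effect_ko, 0)),
      data.frame(gene_id = genes, contrast = "aCD3aCD28_vs_aCD3",
                 planted_lfc = ifelse(is_module, config$module_effect, 0))
    )
    truth$module_gene_ids <- module
    truth$planted_lfc <- lfc
    structure(list(counts = counts, samples = design, truth = truth),
              class = "sim_counts")
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits GFF3 annotations, FASTA sequences, one BED6 per genotype, a counts
#' TSV, a sample metadata TSV, truth tables and a flat key=value manifest.
#' The emitted files round-trip losslessly through the package readers.
#'
#' @param txome A `sim_transcriptome`.
#' @param readsets Named list of [read_set()] objects (names = genotypes).
#' @param sim_counts A `sim_counts` object (or `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @return Named list (the manifest: relative paths plus the seed),
#'   invisibly written to `manifest.txt`.
#' @export
write_fixture <- function(txome, readsets, sim_counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(seed = txome$config$seed)
  write_gff(txome$annotations, file.path(dir, "annotations.gff3"))
  manifest$annotations <- "annotations.gff3"
  write_fasta(txome$sequences, file.path(dir, "sequences.fa"))
  manifest$sequences <- "sequences.fa"
  for (g in names(readsets)) {
    fn <- sprintf("reads_%s.bed", g)
    write_bed(readsets[[g]], file.path(dir, fn))
    manifest[[paste0("reads_", g)]] <- fn
  }
  truth <- txome$truth
  if (!is.null(sim_counts)) {
    write_counts_tsv(sim_counts$counts, file.path(dir, "counts.tsv"))
    write_tsv_file(sim_counts$samples, file.path(dir, "samples.tsv"))
    manifest$counts <- "counts.tsv"
    manifest$samples <- "samples.tsv"
    truth <- sim_counts$truth
    write_tsv_file(truth$planted_lfc, file.path(dir, "truth_lfc.tsv"))
    manifest$truth_lfc <- "truth_lfc.tsv"
  }
  write_tsv_file(truth$sites, file.path(dir, "truth_sites.tsv"))
  manifest$truth_sites <- "truth_sites.tsv"
  roles <- rbind(
    data.frame(gene_id = truth$sponge_id, role = "sponge"),
    data.frame(gene_id = truth$target_gene_ids, role = "target"),
    if (length(truth$module_gene_ids)) {
      data.frame(gene_id = truth$module_gene_ids, role = "module")
    }
  )
  write_tsv_file(roles, file.path(dir, "truth_genes.tsv"))
  manifest$truth_genes <- "truth_genes.tsv"
  writeLines(format_kv(manifest), file.path(dir, "manifest.txt"))
  invisible(manifest)
}
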