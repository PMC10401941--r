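# The core occupancy statistic: canonical miRNA seed-site discovery,
# experimentally supported site filtering, per-3'UTR normalized seed-site
# occupancy fractions, and the genotype comparison of those fractions on
# the logit scale with a paired t-test, plus a multi-family control screen.

#' Define a miRNA seed family
#'
#' @param family_id Family label, e.g. `"miR-15/16"`.
#' @param seed7 7-nt sequence of miRNA positions 2-8, RNA or DNA alphabet.
#' @return A list of class `seed_family`.
#' @export
seed_family <- function(family_id, seed7) {
  s <- as_dna(seed7, "seed7")
  if (nchar(s) != 7L) stop("seed7 must be exactly 7 nt (miRNA positions 2-8)")
  structure(list(family_id = family_id, seed7 = s), class = "seed_family")
}

#' Find canonical seed sites in a 3'UTR sequence
#'
#' Canonical TargetScan-style match classes, written 5'->3' on the target:
#' the 6mer is the reverse complement of miRNA positions 2-7; the 7mer-m8
#' adds the complement of position 8 in front; the 7mer-A1 instead appends
#' an A opposite position 1; the 8mer has both. When one locus satisfies
#' several definitions only the best class is reported
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). T and U are equivalent.
#'
#' @param sequence UTR (or lncRNA) sequence, 5'->3'.
#' @param family A [seed_family()].
#' @param gene_id,utr_id Optional identifiers copied into the output.
#' @return A site table: site_id, gene_id, utr_id, family_id, match_type,
#'   start, end (0-based half-open within the sequence).
#' @examples
#' fam <- seed_family("miR-15/16", "AGCAGCA")
#' find_seed_sites("AAATGCTGCTAAA", fam)  # one 8mer at [3,11)
#' @export
find_seed_sites <- function(sequence, family, gene_id = NA_character_,
                            utr_id = NA_character_) {
  stopifnot(inherits(family, "seed_family"))
  seq <- as_dna(sequence, "UTR sequence")
  core <- revcomp_dna(substr(family$seed7, 1, 6))   # rc of positions 2-7
  m8 <- comp_dna(substr(family$seed7, 7, 7))        # complement of position 8
  n <- nchar(seq)
  empty <- data.frame(site_id = character(0), gene_id = character(0),
                      utr_id = character(0), family_id = character(0),
                      match_type = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  hits <- gregexpr(paste0("(?=", core, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  hits <- as.integer(hits)
  rows <- lapply(hits, function(s) {        # s: 1-based core start
    has_m8 <- s >= 2L && substr(seq, s - 1L, s - 1L) == m8
    has_a1 <- s + 6L <= n && substr(seq, s + 6L, s + 6L) == "A"
    if (has_m8 && has_a1) {
      c(type = "8mer", start = s - 2L, end = s + 6L)
    } else if (has_m8) {
      c(type = "7mer-m8", start = s - 2L, end = s + 5L)
    } else if (has_a1) {
      c(type = "7mer-A1", start = s - 1L, end = s + 6L)
    } else {
      c(type = "6mer", start = s - 1L, end = s + 5L)
    }
  })
  start <- vapply(rows, function(r) as.numeric(r["start"]), numeric(1))
  end <- vapply(rows, function(r) as.numeric(r["end"]), numeric(1))
  type <- vapply(rows, function(r) r[["type"]], character(1))
  data.frame(
    site_id = sprintf("site_%s_%s_%d", gene_id,
                      gsub("[^A-Za-z0-9]", "", family$family_id), start),
    gene_id = gene_id, utr_id = utr_id, family_id = family$family_id,
    match_type = type, start = start, end = end, stringsAsFactors = FALSE
  )
}

#' Scan many UTR sequences for one family's sites
#'
#' @param sequences Named character vector (names are UTR/transcript ids).
#' @param family A [seed_family()].
#' @param gene_ids Optional gene ids parallel to `sequences` (defaults to
#'   the sequence names).
#' @param utrs Optional annotation data.frame; when given, site coordinates
#'   are lifted to genomic coordinates using the matching UTR interval and
#'   `contig` is added.
#' @return A combined site table.
#' @export
scan_seed_sites <- function(sequences, family, gene_ids = NULL, utrs = NULL) {
  ids <- names(sequences)
  if (is.null(gene_ids)) gene_ids <- sub("_UTR$", "", ids)
  tabs <- lapply(seq_along(sequences), function(i) {
    find_seed_sites(sequences[[i]], family, gene_id = gene_ids[i], utr_id = ids[i])
  })
  out <- do.call(rbind, tabs)
  if (!is.null(utrs) && nrow(out)) {
    j <- match(out$utr_id, utrs$name)
    if (anyNA(j)) {
      stop(sprintf("UTR(s) absent from annotations: %s",
                   paste(unique(out$utr_id[is.na(j)]), collapse = ", ")))
    }
    out$contig <- utrs$contig[j]
    out$start <- utrs$start[j] + out$start
    out$end <- utrs$start[j] + out$end
    out$strand <- "+"
  }
  rownames(out) <- NULL
  out
}

#' Keep sites with CLIP support in all required genotypes
#'
#' A site is supported when at least one read overlaps it by at least
#' `min_overlap` nt (default 8, the full 8-mer, so that 1-nt grazing
#' overlaps do not count as support) in every required genotype.
#'
#' @param sites Site table with genomic `contig`/`start`/`end`.
#' @param reads_by_genotype Named list of [read_set()] objects.
#' @param required Genotypes that must each support the site
#'   (default `c("WT", "scr")`).
#' @param min_overlap Minimum read/site intersection in nt.
#' @return The supported subset, with attributes `n_sites` and
#'   `n_distinct_genes`.
#' @export
supported_sites <- function(sites, reads_by_genotype, required = c("WT", "scr"),
                            min_overlap = 8) {
  missing <- setdiff(required, names(reads_by_genotype))
  if (length(missing)) {
    stop(sprintf("read sets missing for genotype(s): %s", paste(missing, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(sites))
  site_iv <- intervals(sites$contig, sites$start, sites$end, name = sites$site_id)
  for (g in required) {
    keep <- keep & (count_overlaps(reads_by_genotype[[g]], site_iv,
                                   min_overlap = min_overlap) >= 1L)
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites") <- nrow(out)
  attr(out, "n_distinct_genes") <- length(unique(out$gene_id))
  out
}

#' Per-3'UTR normalized seed-site occupancy fractions
#'
#' For each site, the reads at the site are divided by the total reads in
#' the site's 3'UTR for the same genotype: the per-site, library-size-free
#' binding statistic. Multiple sites in one UTR share the denominator.
#' Records whose UTR has zero reads are flagged undefined and excluded
#' downstream (their count is reported in the `n_undefined` attribute).
#'
#' @param reads A [read_set()].
#' @param sites Site table with genomic coordinates and `utr_id`.
#' @param utrs Annotation data.frame holding the UTR (or lncRNA) intervals
#'   named by `utr_id`.
#' @param min_overlap Minimum read/site intersection counted at the site
#'   (default 8; the UTR denominator always uses 1).
#' @return data.frame: site_id, genotype, site_reads, utr_reads, fraction,
#'   logit_fraction, defined.
#' @export
site_occupancy_fractions <- function(reads, sites, utrs, min_overlap = 8) {
  rs <- if (inherits(reads, "read_set")) reads else read_set(reads)
  j <- match(sites$utr_id, utrs$name)
  if (anyNA(j)) {
    stop(sprintf("parent UTR(s) missing from annotations: %s",
                 paste(unique(sites$utr_id[is.na(j)]), collapse = ", ")))
  }
  site_iv <- intervals(sites$contig, sites$start, sites$end, name = sites$site_id)
  utr_iv <- intervals(utrs$contig[j], utrs$start[j], utrs$end[j], name = utrs$name[j])
  site_reads <- count_overlaps(rs, site_iv, min_overlap = min_overlap)
  utr_reads <- count_overlaps(rs, utr_iv, min_overlap = 1)
  frac <- ifelse(utr_reads > 0, site_reads / utr_reads, NA_real_)
  out <- data.frame(
    site_id = sites$site_id, genotype = rs$genotype,
    site_reads = site_reads, utr_reads = utr_reads,
    fraction = frac, logit_fraction = logit_fraction(frac),
    defined = utr_reads > 0, stringsAsFactors = FALSE
  )
  attr(out, "n_undefined") <- sum(!out$defined)
  out
}

#' Clamped logit transform of a fraction
#'
#' `ln(f'/(1 - f'))` with `f' = min(max(f, epsilon), 1 - epsilon)`. The
#' clamp keeps boundary fractions (0 and 1) in the paired test.
#'
#' @param fraction Numeric in `[0, 1]` (NA passed through).
#' @param epsilon Clamp width (default 1e-3).
#' @return Numeric vector.
#' @examples
#' logit_fraction(0.5)  # 0
#' logit_fraction(1)    # log(0.999/0.001)
#' @export
logit_fraction <- function(fraction, epsilon = 1e-3) {
  f <- pmin(pmax(fraction, epsilon), 1 - epsilon)
  log(f / (1 - f))
}

#' Paired genotype comparison of site occupancy fractions
#'
#' Two-sided paired t-test on the per-site differences of logit fractions
#' (`d_i = logit_B - logit_A`), with summary means and the percent change
#' reported on the raw fraction scale. Undefined records (zero-read UTRs)
#' are dropped pairwise. Zero-variance differences are handled by
#' convention: p = 0 when all `d_i` are nonzero (a uniform shift), p = 1
#' when all are zero (identical fractions).
#'
#' @param records_a,records_b Outputs of [site_occupancy_fractions()] for
#'   the two genotypes, matched 1:1 by `site_id`.
#' @param epsilon Logit clamp used (recorded in the result).
#' @return A list of class `paired_occupancy_test`: n_sites,
#'   mean_fraction_a, mean_fraction_b, percent_change, t_statistic, df,
#'   p_value, epsilon.
#' @export
paired_occupancy_test <- function(records_a, records_b, epsilon = 1e-3) {
  unmatched <- c(setdiff(records_a$site_id, records_b$site_id),
                 setdiff(records_b$site_id, records_a$site_id))
  if (length(unmatched)) {
    stop(sprintf("unmatched site ids: %s", paste(unique(unmatched), collapse = ", ")))
  }
  b <- records_b[match(records_a$site_id, records_b$site_id), , drop = FALSE]
  ok <- records_a$defined & b$defined
  a <- records_a[ok, , drop = FALSE]
  b <- b[ok, , drop = FALSE]
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 paired sites with defined fractions")
  d <- logit_fraction(b$fraction, epsilon) - logit_fraction(a$fraction, epsilon)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
    p <- if (all(d == 0)) 1 else 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  ma <- mean(a$fraction); mb <- mean(b$fraction)
  structure(list(
    n_sites = n, mean_fraction_a = ma, mean_fraction_b = mb,
    percent_change = 100 * (mb - ma) / ma,
    t_statistic = t_stat, df = n - 1, p_value = p, epsilon = epsilon
  ), class = "paired_occupancy_test")
}

#' @export
print.paired_occupancy_test <- function(x, ...) {
  cat(sprintf(
    "paired occupancy test: n=%d sites, mean fraction %.4f -> %.4f (%+.1f%%), t=%.3f (df=%d), p=%.3g\n",
    x$n_sites, x$mean_fraction_a, x$mean_fraction_b, x$percent_change,
    x$t_statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' Occupancy-shift screen across seed families
#'
#' Runs the supported-site / fraction / paired-test chain for every family
#' and adjusts the p-values across families with Benjamini-Hochberg.
#' Families with fewer than 2 supported sites are flagged untestable.
#'
#' @param families List of [seed_family()] objects.
#' @param reads_by_genotype Named list of [read_set()] objects.
#' @param sites_by_family Named list of site tables (genomic coordinates),
#'   one per family id.
#' @param pair Length-2 genotype vector `c(A, B)`; the test is B vs A.
#' @param utrs Annotation data.frame with the UTR intervals.
#' @param support_required Genotypes a site must be supported in
#'   (default the tested pair).
#' @param min_overlap Site support/counting overlap (default 8).
#' @return data.frame: one row per family with n_sites, mean fractions,
#'   percent_change, t, p, padj, testable.
#' @export
control_family_screen <- function(families, reads_by_genotype, sites_by_family,
                                  pair = c("WT", "scr"), utrs,
                                  support_required = pair, min_overlap = 8) {
  stopifnot(length(families) >= 1L)
  rows <- lapply(families, function(fam) {
    sites <- sites_by_family[[fam$family_id]]
    if (is.null(sites) || nrow(sites) == 0L) {
      return(data.frame(family_id = fam$family_id, n_sites = 0L,
                        mean_fraction_a = NA, mean_fraction_b = NA,
                        percent_change = NA, t_statistic = NA,
                        p_value = NA, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    supp <- supported_sites(sites, reads_by_genotype, required = support_required,
                            min_overlap = min_overlap)
    if (nrow(supp) < 2L) {
      return(data.frame(family_id = fam$family_id, n_sites = nrow(supp),
                        mean_fraction_a = NA, mean_fraction_b = NA,
                        percent_change = NA, t_statistic = NA,
                        p_value = NA, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    rec_a <- site_occupancy_fractions(reads_by_genotype[[pair[1]]], supp, utrs,
                                      min_overlap = min_overlap)
    rec_b <- site_occupancy_fractions(reads_by_genotype[[pair[2]]], supp, utrs,
                                      min_overlap = min_overlap)
    tst <- paired_occupancy_test(rec_a, rec_b)
    data.frame(family_id = fam$family_id, n_sites = tst$n_sites,
               mean_fraction_a = tst$mean_fraction_a,
               mean_fraction_b = tst$mean_fraction_b,
               percent_change = tst$percent_change,
               t_statistic = tst$t_statistic, p_value = tst$p_value,
               testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  testable <- which(out$testable)
  if (length(testable)) out$padj[testable] <- bh_adjust(out$p_value[testable])
  rownames(out) <- NULL
  out
}
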