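# Independent brute-force oracles (per-base set arithmetic) and random
# instance generators used by the property and equivalence tests. These are
# deliberately naive: every operation is expressed over explicit base
# positions so the oracles share no code path with the package.

# Integer base positions covered by an interval row: start .. end-1.
bases_of <- function(contig, start, end) {
  paste0(contig, ":", seq(start, end - 1))
}

# Per-base subtraction: keep the parts of each a-row not covered by b.
oracle_subtract <- function(a, b) {
  covered <- unlist(lapply(seq_len(nrow(b)), function(i) {
    bases_of(b$contig[i], b$start[i], b$end[i])
  }))
  out <- list()
  for (i in seq_len(nrow(a))) {
    pos <- seq(a$start[i], a$end[i] - 1)
    keep <- !(bases_of(a$contig[i], a$start[i], a$end[i]) %in% covered)
    if (!any(keep)) next
    runs <- split(pos[keep], cumsum(c(TRUE, diff(pos[keep]) != 1)))
    for (r in runs) {
      out[[length(out) + 1]] <- data.frame(
        contig = a$contig[i], start = min(r), end = max(r) + 1,
        name = a$name[i], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(data.frame(contig = character(0), start = numeric(0),
                                        end = numeric(0), name = character(0)))))
}

# Per-base overlap length between one read and one target.
oracle_overlap_len <- function(r_contig, r_s, r_e, t_contig, t_s, t_e) {
  if (r_contig != t_contig) return(0)
  length(intersect(seq(r_s, r_e - 1), seq(t_s, t_e - 1)))
}

oracle_count <- function(reads, target, min_overlap = 1) {
  sum(vapply(seq_len(nrow(reads)), function(i) {
    oracle_overlap_len(reads$contig[i], reads$start[i], reads$end[i],
                       target$contig, target$start, target$end) >= min_overlap
  }, logical(1)))
}

oracle_coverage <- function(reads, region) {
  pos <- seq(region$start, region$end - 1)
  depth <- integer(length(pos))
  for (i in seq_len(nrow(reads))) {
    if (reads$contig[i] != region$contig) next
    hit <- pos >= reads$start[i] & pos < reads$end[i]
    depth[hit] <- depth[hit] + 1L
  }
  depth
}

# Per-read assignment oracle for annotation totals with optional masking:
# a read counts toward an annotation iff it covers >= 1 unmasked base of it.
oracle_totals <- function(reads, annotations, mask = NULL) {
  masked <- if (!is.null(mask) && nrow(mask)) {
    unlist(lapply(seq_len(nrow(mask)), function(i) {
      bases_of(mask$contig[i], mask$start[i], mask$end[i])
    }))
  } else {
    character(0)
  }
  vapply(seq_len(nrow(annotations)), function(j) {
    ann_bases <- setdiff(bases_of(annotations$contig[j], annotations$start[j],
                                  annotations$end[j]), masked)
    sum(vapply(seq_len(nrow(reads)), function(i) {
      any(bases_of(reads$contig[i], reads$start[i], reads$end[i]) %in% ann_bases)
    }, logical(1)))
  }, numeric(1))
}

# Random instance generators (small coordinates keep per-base oracles cheap).
random_intervals <- function(n, contigs = c("c1", "c2"), max_pos = 300,
                             max_len = 40) {
  s <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  intervals(sample(contigs, n, replace = TRUE), s, s + len,
            name = sprintf("iv%03d", seq_len(n)))
}

# A small planted transcriptome + reads for recovery tests.
small_sim <- function(seed, ...) {
  sim_config(n_mrna = 40, n_lncrna = 3, n_target_genes = 15,
             n_families = 2, n_control_sites = 10, seed = seed, ...)
}

utrs_of <- function(tx) tx$annotations[tx$annotations$feature_class == "three_prime_UTR", ]

# reads with `count` starts in each consecutive bin of width `bin`
reads_from_bins <- function(counts, bin = 30, contig = "c1") {
  starts <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] > 0) (i - 1) * bin + sample(0:(bin - 1), counts[i], replace = TRUE)
    else integer(0)
  }))
  intervals(contig, starts, starts + 30)
}
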