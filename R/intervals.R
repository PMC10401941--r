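# Genomic interval containers and interval algebra.
#
# All intervals are 0-based, half-open [start, end), the BED convention.
# The user-facing container is a plain data.frame with columns
# contig/start/end/name/score/strand; operations convert to GRanges
# internally where that is the natural engine.

#' Construct a genomic interval table
#'
#' @param contig Character vector of contig (chromosome) names.
#' @param start,end Integer vectors; 0-based half-open coordinates,
#'   `0 <= start < end`.
#' @param name Interval identifiers (recycled).
#' @param score Numeric score column (recycled).
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @return A data.frame with columns contig, start, end, name, score, strand.
#' @examples
#' intervals("chr1", 10, 40, name = "r1")
#' @export
intervals <- function(contig, start, end, name = ".", score = 0, strand = ".") {
  n <- length(start)
  rec <- function(x) if (n == 0L) x[0] else rep_len(x, n)
  df <- data.frame(
    contig = rec(as.character(contig)),
    start = as.numeric(start),
    end = rec(as.numeric(end)),
    name = rec(as.character(name)),
    score = rec(as.numeric(score)),
    strand = rec(as.character(strand)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval table") {
  needed <- c("contig", "start", "end")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("%s lacks column(s): %s", what, paste(missing, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(!nzchar(df$contig)) || anyNA(df$contig)) stop(sprintf("%s: empty contig name", what))
    if (anyNA(df$start) || anyNA(df$end)) stop(sprintf("%s: NA coordinates", what))
    if (any(df$start < 0)) stop(sprintf("%s: negative start", what))
    if (any(df$start >= df$end)) {
      i <- which(df$start >= df$end)[1]
      stop(sprintf("%s: start >= end at row %d (%s:%g-%g)", what, i,
                   df$contig[i], df$start[i], df$end[i]))
    }
  }
  invisible(df)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  gr
}

from_granges <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- S4Vectors::mcols(gr)$name
  intervals(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (is.null(nm)) "." else nm,
    strand = strand
  )
}

# Merge overlapping/adjacent intervals on one contig; returns matrix cols s,e.
merge_starts_ends <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  if (length(s) <= 1L) return(cbind(s = s, e = e))
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  cbind(s = c(out_s, ms), e = c(out_e, me))
}

#' Subtract one interval set from another
#'
#' Returns, for each record of `a`, the parts not covered by any interval in
#' `b` (repeat masking by interval subtraction). The output is sorted within
#' each input record and non-overlapping per record; the total output length
#' equals `length(a) - length(a intersect b)` record-wise. Strand is ignored.
#'
#' @param a,b Interval data.frames (see [intervals()]).
#' @return An interval data.frame; the `name` of each piece is inherited from
#'   the `a` record it came from.
#' @examples
#' a <- intervals("chr1", 0, 100, name = "x")
#' b <- intervals("chr1", 40, 60)
#' subtract_intervals(a, b)  # [0,40) and [60,100)
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a, "a")
  if (nrow(a) == 0L) return(a)
  if (is.null(b) || nrow(b) == 0L) return(a)
  validate_intervals(b, "b")
  merged <- lapply(split(seq_len(nrow(b)), b$contig), function(idx) {
    merge_starts_ends(b$start[idx], b$end[idx])
  })
  pieces <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    m <- merged[[a$contig[i]]]
    s <- a$start[i]; e <- a$end[i]
    if (is.null(m)) {
      keep_s <- s; keep_e <- e
    } else {
      hit <- m[m[, "e"] > s & m[, "s"] < e, , drop = FALSE]
      if (nrow(hit) == 0L) {
        keep_s <- s; keep_e <- e
      } else {
        bs <- pmax(hit[, "s"], s); be <- pmin(hit[, "e"], e)
        keep_s <- c(s, be)
        keep_e <- c(bs, e)
        ok <- keep_s < keep_e
        keep_s <- keep_s[ok]; keep_e <- keep_e[ok]
      }
    }
    if (length(keep_s)) {
      pieces[[i]] <- data.frame(
        contig = a$contig[i], start = keep_s, end = keep_e,
        name = if ("name" %in% names(a)) a$name[i] else ".",
        score = if ("score" %in% names(a)) a$score[i] else 0,
        strand = if ("strand" %in% names(a)) a$strand[i] else ".",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) {
    out <- intervals(character(0), numeric(0), numeric(0))[0, ]
  }
  rownames(out) <- NULL
  out
}

#' Count reads overlapping each target interval
#'
#' A read counts toward a target when the intersection length is at least
#' `min_overlap` nucleotides. Strand is ignored by default; set
#' `strand_match = TRUE` to require matching strands. A read overlapping two
#' targets counts toward both.
#'
#' @param reads A [read_set()] or interval data.frame of reads.
#' @param targets Interval data.frame of target regions.
#' @param min_overlap Minimum intersection length in nt (default 1).
#' @param strand_match Require identical strand (default `FALSE`).
#' @return Integer vector, one count per row of `targets`.
#' @examples
#' r <- intervals("chr1", c(0, 50), c(30, 80))
#' count_overlaps(r, intervals("chr1", 25, 55))               # 2
#' count_overlaps(r, intervals("chr1", 25, 55), min_overlap = 6)  # 1
#' @export
count_overlaps <- function(reads, targets, min_overlap = 1, strand_match = FALSE) {
  stopifnot(min_overlap >= 1)
  reads <- reads_of(reads)
  validate_intervals(targets, "targets")
  if (nrow(reads) == 0L || nrow(targets) == 0L) return(integer(nrow(targets)))
  GenomicRanges::countOverlaps(
    as_granges(targets), as_granges(reads),
    minoverlap = min_overlap, ignore.strand = !strand_match
  )
}

#' Per-base read depth over a region
#'
#' @param reads A [read_set()] or interval data.frame.
#' @param region One-row interval data.frame.
#' @return Integer vector of length `region$end - region$start`; element i is
#'   the number of reads covering base `region$start + i - 1`. Its sum equals
#'   the summed per-read overlap lengths with the region.
#' @export
coverage_track <- function(reads, region) {
  validate_intervals(region, "region")
  stopifnot(nrow(region) == 1L)
  reads <- reads_of(reads)
  len <- as.integer(region$end - region$start)
  depth <- integer(len)
  if (nrow(reads) == 0L) return(depth)
  r <- reads[reads$contig == region$contig &
               reads$end > region$start & reads$start < region$end, , drop = FALSE]
  if (nrow(r) == 0L) return(depth)
  s <- pmax(r$start, region$start) - region$start
  e <- pmin(r$end, region$end) - region$start
  d <- integer(len + 1L)
  for (i in seq_along(s)) {
    d[s[i] + 1L] <- d[s[i] + 1L] + 1L
    d[e[i] + 1L] <- d[e[i] + 1L] - 1L
  }
  cumsum(d[seq_len(len)])
}

#' Construct a CLIP read set
#'
#' @param reads Interval data.frame of aligned read intervals.
#' @param library_id Library identifier.
#' @param genotype Genotype label, e.g. `"WT"`, `"scr"`, `"ko"`.
#' @return An object of class `read_set`: a list with elements `reads`,
#'   `library_id`, `genotype`, `total_reads`.
#' @export
read_set <- function(reads, library_id = "lib", genotype = NA_character_) {
  validate_intervals(reads, "reads")
  structure(
    list(reads = reads, library_id = library_id, genotype = genotype,
         total_reads = nrow(reads)),
    class = "read_set"
  )
}

# Accept either a read_set or a bare interval data.frame.
reads_of <- function(x) {
  if (inherits(x, "read_set")) x$reads else {
    validate_intervals(x, "reads")
    x
  }
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s' (genotype %s): %d reads\n",
              x$library_id, x$genotype, x$total_reads))
  invisible(x)
}
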