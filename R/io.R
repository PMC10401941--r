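# Readers and writers for BED6, GFF3, FASTA and the pipeline's TSV tables.
# GFF3 I/O goes through rtracklayer; FASTA through Biostrings. BED is read
# as a plain tab table with a validation layer that reports offending line
# numbers, which the generic importers do not surface.

#' Read a BED3/BED6 file of aligned read intervals
#'
#' BED convention: 0-based half-open coordinates. With fewer than six
#' columns, name defaults to ".", score to 0 and strand to ".". Input order
#' is preserved.
#'
#' @param path Path to a BED file.
#' @param genotype Optional genotype label recorded on the returned set.
#' @param library_id Library identifier (defaults to the file name).
#' @return A [read_set()].
#' @export
read_bed <- function(path, genotype = NA_character_, library_id = NULL) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(read_set(intervals(character(0), numeric(0), numeric(0)),
                    library_id = library_id %||% basename(path), genotype = genotype))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(ncol < 3L)[1]))
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get_col(2L, NA)))
  end <- suppressWarnings(as.numeric(get_col(3L, NA)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinate", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end", bad[1]))
  }
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  df <- intervals(
    contig = get_col(1L, "."), start = start, end = end,
    name = get_col(4L, "."), score = score, strand = get_col(6L, ".")
  )
  read_set(df, library_id = library_id %||% basename(path), genotype = genotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write intervals as BED6
#'
#' @param x A [read_set()] or interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- reads_of(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$contig, as.integer(df$start), as.integer(df$end),
                   df$name, format(df$score, trim = TRUE, scientific = FALSE),
                   df$strand)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# GFF3 type <-> internal feature_class mapping. Unknown types map to
# "other" with a warning; "gene" is a recognized structural type that is
# carried through as class "other" silently.
GFF_TYPE_TO_CLASS <- c(
  lncRNA = "lncRNA", lnc_RNA = "lncRNA",
  three_prime_UTR = "three_prime_UTR",
  exon = "exon", intron = "intron", CDS = "CDS",
  repeat_region = "repeat", gene = "other", region = "other"
)
CLASS_TO_GFF_TYPE <- c(
  lncRNA = "lnc_RNA", three_prime_UTR = "three_prime_UTR",
  exon = "exon", intron = "intron", CDS = "CDS",
  "repeat" = "repeat_region", other = "region"
)

#' Read a GFF3 annotation file
#'
#' GFF3 is 1-based inclusive; coordinates are converted to the internal
#' 0-based half-open convention. The GFF type column is mapped to a
#' `feature_class` in `{lncRNA, three_prime_UTR, exon, intron, CDS, repeat,
#' other}`; unknown types become `"other"` with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return An annotation data.frame: interval columns plus `feature_class`
#'   and `gene_id` (from the `Parent` attribute where present).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  cls <- unname(GFF_TYPE_TO_CLASS[type])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning(sprintf("unknown GFF3 feature type(s) classified 'other': %s",
                    paste(unique(type[unknown]), collapse = ", ")))
    cls[unknown] <- "other"
  }
  id <- gr$ID
  if (is.null(id)) id <- rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- intervals(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = ifelse(is.na(id), ".", id),
    strand = strand
  )
  df$feature_class <- cls
  df$gene_id <- parent
  df
}

#' Write an annotation data.frame as GFF3
#'
#' @param annotations Annotation data.frame with a `feature_class` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotations, path) {
  validate_intervals(annotations, "annotations")
  stopifnot("feature_class" %in% names(annotations))
  type <- CLASS_TO_GFF_TYPE[annotations$feature_class]
  type[is.na(type)] <- "region"
  gr <- as_granges(annotations)
  S4Vectors::mcols(gr) <- NULL
  gr$source <- "ceRNAclip"
  gr$type <- factor(type)
  gr$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  gr$ID <- annotations$name
  if ("gene_id" %in% names(annotations)) {
    gr$Parent <- IRanges::CharacterList(
      lapply(annotations$gene_id, function(g) if (is.na(g)) character(0) else g)
    )
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column must be `gene_id`; remaining header fields are sample ids.
#' Counts must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column of counts TSV must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (!is.numeric(m)) stop("non-numeric count encountered")
  if (any(m < 0)) stop("negative count encountered")
  if (any(m != floor(m))) stop("non-integer count encountered")
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#' @param counts Gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns sample_id, genotype, stimulation (and
#'   optionally replicate).
#' @param counts Optional count matrix; if given, sample ids are required to
#'   match its column names exactly.
#' @return A data.frame of sample metadata.
#' @export
read_sample_table <- function(path, counts = NULL) {
  if (!file.exists(path)) stop(sprintf("sample table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "genotype", "stimulation")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("sample table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!is.null(counts)) {
    only_meta <- setdiff(df$sample_id, colnames(counts))
    only_counts <- setdiff(colnames(counts), df$sample_id)
    if (length(only_meta) || length(only_counts)) {
      stop(sprintf(
        "sample mismatch; missing from counts: [%s]; missing from metadata: [%s]",
        paste(only_meta, collapse = ", "), paste(only_counts, collapse = ", ")
      ))
    }
  }
  df
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write named sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
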