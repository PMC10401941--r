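# Internal helpers: seeded RNG scoping, seed derivation, sequence utilities.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state
#' so that seeded helpers do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit string hash (Horner scheme mod 2^31 - 1).
# Exact in double arithmetic: intermediate values stay below 2^53.
hash_label <- function(label) {
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  h
}

#' Derive a stream-specific seed from a master seed
#'
#' Each (stage, genotype) random stream gets its own seed derived from the
#' master seed and a text label, so adding a genotype or a stage does not
#' perturb the draws of the others.
#'
#' @param seed Master integer seed.
#' @param label Character stream label, e.g. `"clip_WT"`.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  as.integer(((seed %% 2147483647) * 48271 + hash_label(label)) %% 2147483647)
}

# Reverse complement of a DNA string (A/C/G/T, T written for U).
revcomp_dna <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

comp_dna <- function(x) chartr("ACGT", "TGCA", x)

# RNA -> DNA alphabet, uppercased, validated.
as_dna <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(chartr("U", "T", x))
  bad <- gsub("[ACGT]", "", x)
  if (any(nzchar(bad))) {
    stop(sprintf("invalid character(s) '%s' in %s", substr(bad[nzchar(bad)][1], 1, 5), what))
  }
  x
}

# Stable key=value formatting used by manifests and reports.
format_kv <- function(x) {
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) paste(format(v, digits = 10, trim = TRUE, scientific = FALSE), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  paste0(names(x), "=", vals)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
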