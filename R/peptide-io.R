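#' Read per-sample peptide reads
#'
#' Reads a sample's peptide list from a plain text file (one peptide per line,
#' with an optional tab-separated read count) or a FASTA file (counts come
#' from duplicated records). Identical peptides are aggregated with summed
#' counts. Sequences failing the length or alphabet check are excluded and
#' tallied in the rejection log.
#'
#' @param path Path to the input file.
#' @param format `"plain"` or `"fasta"`.
#' @param expected_length Required peptide length (default 12).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return An object of class `raw_reads`: a list with `sample_id`,
#'   `peptides` (unique sequences), `counts` (summed read counts) and
#'   `rejected` (named counts of rejected records).
#' @export
read_sample_peptides <- function(path, format = c("plain", "fasta"),
                                 expected_length = 12L, sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))

  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    seqs <- toupper(vapply(parts, `[[`, "", 1L))
    counts <- vapply(parts, function(x) {
      if (length(x) >= 2L) suppressWarnings(as.numeric(x[[2]])) else 1
    }, 0)
    counts[is.na(counts)] <- 1
  } else {
    ss <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(ss))
    counts <- rep(1, length(seqs))
  }
  if (any(counts < 1)) stop("read counts must be positive")

  ok_len <- nchar(seqs) == expected_length
  ok_aa <- grepl(paste0("^[", paste(AA20, collapse = ""), "]*$"), seqs)
  rejected <- c(length = sum(!ok_len), alphabet = sum(ok_len & !ok_aa))
  keep <- ok_len & ok_aa
  seqs <- seqs[keep]
  counts <- counts[keep]
  if (length(seqs) == 0L) stop("no valid peptide records in ", path)

  agg <- rowsum(counts, group = seqs)
  structure(list(sample_id = sample_id,
                 peptides = rownames(agg),
                 counts = as.numeric(agg[, 1L]),
                 rejected = rejected),
            class = "raw_reads")
}

#' @export
print.raw_reads <- function(x, ...) {
  cat("raw_reads '", x$sample_id, "': ", length(x$peptides),
      " unique peptides, ", sum(x$counts), " reads, ",
      sum(x$rejected), " rejected records\n", sep = "")
  invisible(x)
}

#' Construct a peptide set
#'
#' Low-level constructor for a sample's non-redundant peptide set. Peptides
#' are stored sorted so that two sets built from the same sequences compare
#' identical regardless of input order.
#'
#' @param sample_id Sample identifier.
#' @param peptides Character vector of unique, equal-length peptides over the
#'   20 standard amino acids.
#' @return An object of class `peptide_set` with fields `sample_id`,
#'   `peptides`, `N` (number of unique peptides), `peptide_length` and
#'   `profile` (amino-acid frequency profile of the retained peptides).
#' @export
peptide_set <- function(sample_id, peptides) {
  if (length(peptides) == 0L) stop("empty peptide set")
  if (anyDuplicated(peptides)) stop("peptides must be unique")
  len <- nchar(peptides[[1]])
  if (any(nchar(peptides) != len)) stop("peptides must have uniform length")
  peptides <- sort(peptides)
  structure(list(sample_id = sample_id,
                 peptides = peptides,
                 N = length(peptides),
                 peptide_length = len,
                 profile = amino_acid_frequencies(peptides)),
            class = "peptide_set")
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("peptide_set '", x$sample_id, "': N = ", x$N, " unique ",
      x$peptide_length, "-mers\n", sep = "")
  invisible(x)
}

#' Collapse reads into a non-redundant peptide set
#'
#' Duplicate observations of a peptide count once, and peptides within a small
#' Hamming distance of a more abundant retained peptide are treated as
#' sequencing errors and absorbed into it. The collapse is greedy and
#' deterministic: records are processed in order of descending read count
#' (ties broken lexicographically), and each candidate is absorbed by the
#' first already-retained peptide within `max_mutations` substitutions.
#'
#' @param reads A `raw_reads` object from [read_sample_peptides()].
#' @param max_mutations Maximum Hamming distance treated as sequencing error
#'   (default 3). Must satisfy `0 <= max_mutations < peptide length`.
#' @return A [peptide_set()] of the retained peptides.
#' @export
build_nonredundant_set <- function(reads, max_mutations = 3L) {
  stopifnot(inherits(reads, "raw_reads"))
  if (length(reads$peptides) == 0L) stop("no reads to collapse")
  len <- nchar(reads$peptides[[1]])
  if (max_mutations < 0L) stop("max_mutations must be non-negative")
  if (max_mutations >= len) stop("max_mutations must be smaller than the peptide length")

  ord <- order(-reads$counts, reads$peptides)
  peps <- reads$peptides[ord]
  if (max_mutations == 0L) {
    keep <- rep(TRUE, length(peps))
  } else {
    keep <- cpp_collapse(peps, as.integer(max_mutations))
  }
  peptide_set(reads$sample_id, peps[keep])
}

#' Amino-acid frequency profile of a peptide set
#'
#' Computes `f(a)` = occurrences of residue `a` across all positions of all
#' peptides, divided by the total residue count (`N * length`).
#'
#' @param peptides Character vector of equal-length peptides.
#' @return Named numeric vector over [AA20] summing to 1.
#' @export
amino_acid_frequencies <- function(peptides) {
  if (length(peptides) == 0L) stop("empty peptide set")
  counts <- cpp_aa_counts(peptides)
  setNames(counts / sum(counts), AA20)
}

#' Write a peptide set to disk
#'
#' Writes the plain peptide list (one per line) plus a JSON sidecar
#' (`<path>.json`) holding the sample id, N and the frequency profile.
#'
#' @param ps A `peptide_set`.
#' @param path Output path for the peptide list.
#' @return `path`, invisibly.
#' @export
write_peptide_set <- function(ps, path) {
  stopifnot(inherits(ps, "peptide_set"))
  writeLines(ps$peptides, path)
  jsonlite::write_json(
    list(sample_id = ps$sample_id, N = ps$N,
         peptide_length = ps$peptide_length,
         profile = as.list(ps$profile)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
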