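#' Motifs
#'
#' A motif generalizes a pattern: each column is either a wildcard or a
#' non-empty set of allowed residues with positive weights (the weights record
#' how strongly each residue contributed during clustering and define the
#' "most enriched" residue of a column). The printable notation uses `x` for
#' wildcards and square brackets for residue alternatives, e.g.
#' `"QPEQPF[PS]E"`.
#'
#' @param columns List with one element per column: `NULL` for a wildcard, or
#'   a named numeric vector of positive residue weights (names are residues;
#'   order is preserved and used to break weight ties).
#' @return An object of class `imune_motif`.
#' @export
motif <- function(columns) {
  if (length(columns) == 0L) stop("motif must have at least one column")
  if (is.null(columns[[1]]) || is.null(columns[[length(columns)]]))
    stop("first and last motif columns must be defined")
  for (col in columns) {
    if (is.null(col)) next
    if (length(col) == 0L) stop("defined motif columns must be non-empty")
    if (is.null(names(col)) || !all(names(col) %in% AA20))
      stop("motif column residues must be standard amino acids")
    if (any(col <= 0)) stop("motif column weights must be positive")
    if (anyDuplicated(names(col))) stop("duplicate residue in motif column")
  }
  structure(list(columns = columns), class = "imune_motif")
}

#' Parse motif notation
#'
#' @param s Notation string such as `"QPEQPF[PS]E"` or `"VPxLxxxET"`.
#'   Residues parsed from notation get unit weights, in string order.
#' @return An `imune_motif`.
#' @export
parse_motif <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  columns <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      columns[length(columns) + 1L] <- list(NULL)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA20) stop("illegal character in motif: ", s)
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed bracket in motif: ", s)
      if (length(set) == 0L) stop("empty bracket in motif: ", s)
      columns[[length(columns) + 1L]] <- setNames(rep(1, length(set)), set)
      i <- j + 1L
    } else if (ch %in% AA20) {
      columns[[length(columns) + 1L]] <- setNames(1, ch)
      i <- i + 1L
    } else {
      stop("illegal character in motif: ", s)
    }
  }
  motif(columns)
}

#' Render motif notation
#'
#' Single-residue columns print as the residue, multi-residue columns inside
#' brackets ordered by decreasing weight (ties keep the column's stored
#' order), wildcards as `x`. `parse_motif(render_motif(m))` round-trips the
#' column structure.
#'
#' @param m An `imune_motif`.
#' @return Notation string.
#' @export
render_motif <- function(m) {
  stopifnot(inherits(m, "imune_motif"))
  parts <- vapply(m$columns, function(col) {
    if (is.null(col)) return("x")
    res <- names(col)[order(-col, seq_along(col))]
    if (length(res) == 1L) res else paste0("[", paste(res, collapse = ""), "]")
  }, "")
  paste(parts, collapse = "")
}

#' @export
format.imune_motif <- function(x, ...) render_motif(x)

#' @export
print.imune_motif <- function(x, ...) {
  cat("motif ", render_motif(x), " (span ", motif_span(x), ", ",
      motif_defined_count(x), " defined columns)\n", sep = "")
  invisible(x)
}

#' @export
as.character.imune_motif <- function(x, ...) render_motif(x)

#' Motif span and defined-column count
#'
#' @param m An `imune_motif`.
#' @return Integer.
#' @export
motif_span <- function(m) length(m$columns)

#' @rdname motif_span
#' @export
motif_defined_count <- function(m) {
  sum(!vapply(m$columns, is.null, TRUE))
}

#' Coerce a pattern to a motif
#'
#' A pattern is exactly a motif with singleton residue columns.
#'
#' @param pattern Pattern notation string.
#' @return An `imune_motif`.
#' @export
as_motif <- function(pattern) {
  if (inherits(pattern, "imune_motif")) return(pattern)
  p <- parse_pattern(pattern)
  cols <- lapply(seq_len(p$L), function(i) {
    if (p$defined[i]) setNames(1, p$chars[i]) else NULL
  })
  motif(cols)
}

# internal: per-column residue bitmasks over AA20 (wildcard = all bits)
motif_masks <- function(m) {
  all_mask <- bitwShiftL(1L, 20L) - 1L
  vapply(m$columns, function(col) {
    if (is.null(col)) return(all_mask)
    codes <- match(names(col), AA20) - 1L
    Reduce(bitwOr, bitwShiftL(1L, codes), 0L)
  }, 0L)
}

#' Count motif matches in a peptide
#'
#' Number of offsets at which every non-wildcard column's residue set
#' contains the peptide residue.
#'
#' @param m An `imune_motif` (or pattern/motif notation string).
#' @param peptide Peptide string, at least as long as the motif span.
#' @return Integer number of matching offsets.
#' @export
motif_occurrences_in_peptide <- function(m, peptide) {
  if (is.character(m)) m <- parse_motif(m)
  if (nchar(peptide) < motif_span(m)) stop("peptide shorter than the motif span")
  cpp_motif_hits(peptide, motif_masks(m))[[1]]
}

#' Column agreement between a motif and a reference motif
#'
#' Slides the motif along the reference and reports the maximum number of
#' reference columns whose residue sets are exactly reproduced (wildcard
#' columns must pair with wildcards or lie outside the motif's span only if
#' the reference column is also outside -- in practice: only column pairs
#' with identical residue sets count). Used to quantify recovery of a known
#' planted motif.
#'
#' @param m Candidate `imune_motif` (or notation string).
#' @param reference Reference `imune_motif` (or notation string).
#' @return Integer: matched reference columns at the best offset (between 0
#'   and the reference's span).
#' @export
motif_column_agreement <- function(m, reference) {
  if (is.character(m)) m <- parse_motif(m)
  if (is.character(reference)) reference <- parse_motif(reference)
  col_set <- function(col) if (is.null(col)) character(0) else sort(names(col))
  cm <- lapply(m$columns, col_set)
  cr <- lapply(reference$columns, col_set)
  Lm <- length(cm); Lr <- length(cr)
  best <- 0L
  for (off in seq.int(-(Lm - 1L), Lr - 1L)) {
    hits <- 0L
    for (j in seq_len(Lr)) {
      i <- j - off
      if (i < 1L || i > Lm) next
      if (length(cr[[j]]) > 0L && identical(cm[[i]], cr[[j]])) hits <- hits + 1L
    }
    if (hits > best) best <- hits
  }
  best
}

#' Total motif matches in a peptide set
#'
#' @param m An `imune_motif` (or notation string).
#' @param ps A [peptide_set()].
#' @return Total offset-match count over all peptides.
#' @export
motif_observations <- function(m, ps) {
  if (is.character(m)) m <- parse_motif(m)
  stopifnot(inherits(ps, "peptide_set"))
  if (motif_span(m) > ps$peptide_length) stop("motif span exceeds peptide length")
  cpp_motif_count_multi(ps$peptides, list(motif_masks(m)))[[1]]
}
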