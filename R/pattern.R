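#' Amino-acid patterns
#'
#' A pattern is an ordered template of defined residues possibly interleaved
#' with wildcard positions (written `x`), e.g. `"PEQxP"`. The first and last
#' positions are always defined, the number of defined positions k lies in a
#' configurable band (3-5 by default) and the total span is bounded (10 by
#' default). Patterns are represented throughout by their notation strings.
#'
#' @name patterns
NULL

# internal: parse a notation string into chars/defined flags
parse_pattern <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(AA20, "x"))
  if (any(bad)) stop("illegal character in pattern: ", x)
  defined <- chars != "x"
  list(chars = chars, defined = defined,
       L = length(chars), k = sum(defined))
}

#' Validate pattern notation
#'
#' @param x Pattern notation string.
#' @param k_min,k_max Allowed range for the number of defined positions.
#' @param max_len Maximum span.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_pattern <- function(x, k_min = 3L, k_max = 5L, max_len = 10L) {
  p <- tryCatch(parse_pattern(x), error = function(e) NULL)
  if (is.null(p) || p$L < 1L || p$L > max_len) return(FALSE)
  if (!p$defined[1L] || !p$defined[p$L]) return(FALSE)
  p$k >= k_min && p$k <= k_max
}

# internal: all defined-position layouts (sorted 1-based vectors starting at 1
# and ending at L) for the given bounds, in deterministic order
pattern_layouts <- function(k_min = 3L, k_max = 5L, max_len = 10L) {
  out <- list()
  for (L in seq_len(max_len)) {
    for (k in seq.int(k_min, k_max)) {
      if (k > L) next
      if (k == 1L) {
        if (L == 1L) out[[length(out) + 1L]] <- 1L
        next
      }
      interior <- if (k == 2L) list(integer(0)) else {
        if (L == 2L) next
        v <- seq.int(2L, L - 1L)
        if (length(v) == 1L) list(v) else combn(v, k - 2L, simplify = FALSE)
      }
      for (mid in interior) out[[length(out) + 1L]] <- c(1L, mid, L)
    }
  }
  out
}

#' Size of the pattern space
#'
#' Closed-form count of all patterns with `k_min`-`k_max` defined positions,
#' span at most `max_len`, defined first and last positions, over an alphabet
#' of `alphabet_size` residues: sum over k and span L of
#' `choose(L - 2, k - 2) * alphabet_size^k` (with the degenerate k = 1, 2
#' layouts handled explicitly).
#'
#' @param k_min,k_max Range of defined positions (defaults 3 and 5).
#' @param max_len Maximum span (default 10).
#' @param alphabet_size Number of residues (default 20).
#' @return The number of distinct patterns, as a double.
#' @examples
#' count_pattern_space(3, 5, 10, 20)  # 416928000
#' @export
count_pattern_space <- function(k_min = 3L, k_max = 5L, max_len = 10L,
                                alphabet_size = 20L) {
  if (k_min < 1L || k_min > k_max || k_max > max_len)
    stop("invalid pattern bounds")
  total <- 0
  for (k in seq.int(k_min, k_max)) {
    if (k == 1L) {
      total <- total + alphabet_size
      next
    }
    layouts <- sum(choose(seq.int(k, max_len) - 2, k - 2))
    total <- total + layouts * alphabet_size^k
  }
  total
}

#' Enumerate all patterns
#'
#' Materializes the full pattern space for the given bounds and alphabet.
#' Intended for small alphabets and bounds; refuses to build more than
#' `limit` patterns.
#'
#' @inheritParams count_pattern_space
#' @param alphabet Character vector of residues.
#' @param limit Safety cap on the number of patterns (default 1e7).
#' @return Character vector of pattern notation strings, each exactly once.
#' @export
enumerate_patterns <- function(k_min = 3L, k_max = 5L, max_len = 10L,
                               alphabet = AA20, limit = 1e7) {
  n <- count_pattern_space(k_min, k_max, max_len, length(alphabet))
  if (n > limit) stop("pattern space too large to enumerate (", n, ")")
  layouts <- pattern_layouts(k_min, k_max, max_len)
  out <- vector("list", length(layouts))
  for (i in seq_along(layouts)) {
    pos <- layouts[[i]]
    L <- pos[length(pos)]
    k <- length(pos)
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), k),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    tmpl <- rep("x", L)
    out[[i]] <- apply(as.matrix(grid), 1L, function(res) {
      tmpl[pos] <- res
      paste(tmpl, collapse = "")
    })
  }
  unlist(out, use.names = FALSE)
}

#' Count pattern matches in a peptide
#'
#' Number of offsets at which every defined position of the pattern matches
#' the peptide residue.
#'
#' @param pattern Pattern notation string.
#' @param peptide Peptide string, at least as long as the pattern span.
#' @return Integer number of matching offsets.
#' @examples
#' occurrences_in_peptide("AxA", "AAAAAAAAAAAA")  # 10
#' @export
occurrences_in_peptide <- function(pattern, peptide) {
  p <- parse_pattern(pattern)
  l <- nchar(peptide)
  if (l < p$L) stop("peptide shorter than the pattern span")
  pep <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!all(pep %in% AA20)) stop("invalid residue in peptide")
  hits <- 0L
  idx <- which(p$defined)
  for (off in 0:(l - p$L)) {
    if (all(pep[off + idx] == p$chars[idx])) hits <- hits + 1L
  }
  hits
}

#' Pattern containment
#'
#' Tests whether `child` fits inside `parent`: at some offset every defined
#' position of `child` coincides with an identical defined position of
#' `parent` (wildcards of the contained pattern may sit over anything).
#' Identical patterns contain each other; callers classifying parent/child
#' relationships exclude identity themselves.
#'
#' @param parent,child Pattern notation strings.
#' @return `TRUE` or `FALSE`.
#' @examples
#' pattern_contains("PEQPxP", "PEQP")    # TRUE
#' pattern_contains("PEQPxP", "PEQxxP")  # TRUE
#' pattern_contains("PEQP", "PEQPxP")    # FALSE
#' @export
pattern_contains <- function(parent, child) {
  pp <- parse_pattern(parent)
  pc <- parse_pattern(child)
  if (pc$L > pp$L) return(FALSE)
  idx <- which(pc$defined)
  for (off in 0:(pp$L - pc$L)) {
    if (all(pp$defined[off + idx] & pp$chars[off + idx] == pc$chars[idx]))
      return(TRUE)
  }
  FALSE
}
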