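#' Best-five-positions motif enrichment
#'
#' Sample diversity bounds how many defined positions can carry an expected
#' observation of at least one, so motif enrichment is evaluated over exactly
#' `min(n_positions, defined columns)` defined columns: every subset of that
#' size is reduced to a motif spanning its outermost chosen columns (other
#' columns become wildcards) and the maximum enrichment over subsets is
#' reported. Ties take the lexicographically smallest index subset. A subset
#' that can never be observed in the sample (expected count 0 because a
#' required residue set has zero total frequency) scores 0.
#'
#' @param m An `imune_motif` (or notation string) with at least 3 defined
#'   columns.
#' @param ps A [peptide_set()].
#' @param n_positions Number of defined positions to use (default 5).
#' @return List with `enrichment`, `subset` (indices of the chosen defined
#'   columns within the motif), `O` and `E`.
#' @export
motif_enrichment_top5 <- function(m, ps, n_positions = 5L) {
  if (is.character(m)) m <- parse_motif(m)
  stopifnot(inherits(ps, "peptide_set"))
  defined <- which(!vapply(m$columns, is.null, TRUE))
  if (length(defined) < 3L) stop("motif needs at least 3 defined columns")
  s <- min(n_positions, length(defined))
  subsets <- combn(defined, s, simplify = FALSE)
  # a subset's span is re-derived from its outermost columns; only subsets
  # that fit the peptide are scoreable
  subsets <- Filter(function(sub) max(sub) - min(sub) < ps$peptide_length,
                    subsets)
  if (length(subsets) == 0L) stop("motif span exceeds peptide length")

  all_mask <- bitwShiftL(1L, 20L) - 1L
  full_masks <- motif_masks(m)
  masks_list <- lapply(subsets, function(sub) {
    lo <- min(sub); hi <- max(sub)
    mk <- rep(all_mask, hi - lo + 1L)
    mk[sub - lo + 1L] <- full_masks[sub]
    mk
  })
  O <- cpp_motif_count_multi(ps$peptides, masks_list)
  E <- vapply(seq_along(subsets), function(i) {
    sub <- subsets[[i]]
    L <- max(sub) - min(sub) + 1L
    fac <- vapply(m$columns[sub], function(col) sum(ps$profile[names(col)]), 0)
    ps$N * (ps$peptide_length - L + 1) * prod(fac)
  }, 0)
  R <- ifelse(E > 0, O / E, 0)
  best <- which.max(R)  # first maximum; subsets from combn are lexicographic
  list(enrichment = R[best], subset = subsets[[best]], O = O[best], E = E[best])
}

#' Motif-by-sample enrichment matrix
#'
#' @param panel List of motifs (`imune_motif` or notation strings).
#' @param samples List of [peptide_set()] objects.
#' @param n_positions Positions used per cell (default 5).
#' @return Numeric matrix (motif notations x sample ids) of
#'   best-subset enrichments, with the chosen subsets in attribute
#'   `"subsets"`.
#' @export
evaluate_panel <- function(panel, samples, n_positions = 5L) {
  motifs <- lapply(panel, function(m) if (is.character(m)) parse_motif(m) else m)
  ids <- vapply(samples, function(s) s$sample_id, "")
  out <- matrix(0, nrow = length(motifs), ncol = length(samples),
                dimnames = list(vapply(motifs, render_motif, ""), ids))
  subsets <- list()
  for (i in seq_along(motifs)) {
    for (j in seq_along(samples)) {
      cell <- motif_enrichment_top5(motifs[[i]], samples[[j]], n_positions)
      out[i, j] <- cell$enrichment
      subsets[[paste(rownames(out)[i], ids[j], sep = "|")]] <- cell$subset
    }
  }
  attr(out, "subsets") <- subsets
  out
}

#' Panel classification rule
#'
#' A sample is called positive when at least one panel motif reaches the
#' primary enrichment threshold and (when `require_distinct_motifs`) a
#' different motif reaches the secondary threshold.
#'
#' @param primary_threshold Default 15.
#' @param secondary_threshold Default 5.
#' @param require_distinct_motifs Default `TRUE`.
#' @return An object of class `panel_rule`.
#' @export
panel_rule <- function(primary_threshold = 15, secondary_threshold = 5,
                       require_distinct_motifs = TRUE) {
  if (!(primary_threshold >= secondary_threshold && secondary_threshold > 0))
    stop("need primary_threshold >= secondary_threshold > 0")
  structure(list(primary_threshold = primary_threshold,
                 secondary_threshold = secondary_threshold,
                 require_distinct_motifs = require_distinct_motifs),
            class = "panel_rule")
}

#' Classify one sample from its panel enrichments
#'
#' @param enrichments Numeric vector of one sample's enrichment values over
#'   the panel motifs (a column of [evaluate_panel()]'s matrix).
#' @param rule A [panel_rule()].
#' @return `"positive"` or `"negative"`.
#' @export
classify_sample <- function(enrichments, rule = panel_rule()) {
  stopifnot(inherits(rule, "panel_rule"))
  if (length(enrichments) == 0L) stop("empty panel")
  srt <- sort(enrichments, decreasing = TRUE)
  ok <- srt[1L] >= rule$primary_threshold &&
    (!rule$require_distinct_motifs ||
       (length(srt) >= 2L && srt[2L] >= rule$secondary_threshold))
  if (ok) "positive" else "negative"
}

#' Classify every sample of an enrichment matrix
#'
#' @param matrix A motif-by-sample matrix from [evaluate_panel()].
#' @param rule A [panel_rule()].
#' @return Named character vector (`"positive"`/`"negative"`) per sample.
#' @export
classify_cohort <- function(matrix, rule = panel_rule()) {
  vapply(colnames(matrix), function(id) classify_sample(matrix[, id], rule), "")
}
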