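#' PAM30 substitution matrix restricted to the 20 standard amino acids
#'
#' @return A 20 x 20 integer matrix in [AA20] order (NCBI PAM30, as shipped
#'   with Biostrings).
#' @export
pam30_matrix <- function() {
  e <- new.env()
  utils::data("PAM30", package = "Biostrings", envir = e)
  m <- e$PAM30[AA20, AA20]
  storage.mode(m) <- "integer"
  m
}

#' Build the seed graph of a retained pattern set
#'
#' A motif seed is a retained pattern that contains no other retained
#' pattern; every other retained pattern contains at least one seed (by
#' transitivity of containment) and is a child of each seed it contains.
#'
#' @param patterns Character vector of retained pattern notations.
#' @return An object of class `seed_graph` with elements `patterns`, `seeds`
#'   and `children` (named list: seed -> character vector of its child
#'   patterns). [relate_seeds()] adds alignment edges and ordering.
#' @export
build_seed_graph <- function(patterns) {
  patterns <- unique(patterns)
  if (length(patterns) == 0L) stop("empty retained pattern set")
  pairs <- cpp_containment(patterns)  # rows (i, j): pattern j fits inside i
  is_parent <- seq_along(patterns) %in% pairs[, 1L]
  seeds <- patterns[!is_parent]
  seed_idx <- which(!is_parent)
  hit <- pairs[pairs[, 2L] %in% seed_idx, , drop = FALSE]
  children <- setNames(vector("list", length(seeds)), seeds)
  for (s in seeds) children[[s]] <- character(0)
  if (nrow(hit) > 0L) {
    by_seed <- split(patterns[hit[, 1L]], patterns[hit[, 2L]])
    children[names(by_seed)] <- by_seed
  }
  # parse cache reused by motif construction
  chars <- strsplit(patterns, "", fixed = TRUE)
  def_pos <- lapply(chars, function(ch) which(ch != "x"))
  def_res <- lapply(seq_along(chars), function(i) chars[[i]][def_pos[[i]]])
  names(def_pos) <- names(def_res) <- patterns
  structure(list(patterns = patterns, seeds = seeds, children = children,
                 def_pos = def_pos, def_res = def_res,
                 related = NULL, connected_counts = NULL),
            class = "seed_graph")
}

#' Ungapped PAM30 alignment of two patterns
#'
#' Considers every relative offset with at least one position where both
#' patterns are defined; the frame score sums the substitution matrix over
#' those positions (any position where either pattern is a wildcard
#' contributes 0). Returns the maximum score and the smallest offset
#' achieving it; if no frame overlaps on defined positions the score is
#' `-Inf`.
#'
#' @param a,b Pattern notation strings.
#' @param matrix Substitution matrix (default [pam30_matrix()]).
#' @return List with `score` and `offset` (position of `b`'s first column
#'   relative to `a`'s, 0-based; `NA` when no frame exists).
#' @export
align_pattern_pair <- function(a, b, matrix = pam30_matrix()) {
  pa <- parse_pattern(a)
  pb <- parse_pattern(b)
  best <- -Inf
  best_off <- NA_integer_
  for (off in seq.int(-(pb$L - 1L), pa$L - 1L)) {
    js <- seq_len(pb$L)
    ia <- js + off
    ok <- ia >= 1L & ia <= pa$L
    js <- js[ok]; ia <- ia[ok]
    both <- pb$defined[js] & pa$defined[ia]
    if (!any(both)) next
    sc <- sum(matrix[cbind(pa$chars[ia[both]], pb$chars[js[both]])])
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

#' Relate motif seeds by PAM30 alignment
#'
#' Adds symmetric relatedness edges between seed pairs whose best alignment
#' score reaches `threshold`, then orders the seeds by descending
#' connected-pattern count (the size of the union of the seed's children,
#' its related seeds and their children), ties broken lexicographically.
#'
#' @param graph A `seed_graph` from [build_seed_graph()].
#' @param threshold Minimum alignment score for relatedness (default 5).
#' @param matrix Substitution matrix.
#' @return The graph with `related` (named list seed -> related seeds),
#'   `connected_counts` (named integer vector) and seeds reordered.
#' @export
relate_seeds <- function(graph, threshold = 5L, matrix = pam30_matrix()) {
  stopifnot(inherits(graph, "seed_graph"))
  seeds <- graph$seeds
  n <- length(seeds)
  related <- setNames(vector("list", n), seeds)
  for (s in seeds) related[[s]] <- character(0)
  if (n > 1L) {
    S <- cpp_align_best(seeds, seeds, matrix)$score
    diag(S) <- -Inf
    adj <- is.finite(S) & S >= threshold
    for (i in seq_len(n)) related[[seeds[i]]] <- seeds[adj[i, ]]
  }
  counts <- vapply(seeds, function(s) {
    length(unique(c(graph$children[[s]], related[[s]],
                    unlist(graph$children[related[[s]]], use.names = FALSE))))
  }, 0L)
  # ties (frequent when the relatedness graph is dense) break towards seeds
  # with more direct children: their members anchor at exact containment
  # frames, so their motifs are built on the most reliable alignments
  n_children <- lengths(graph$children)[seeds]
  ord <- order(-counts, -n_children, seeds)
  graph$seeds <- seeds[ord]
  graph$related <- related[graph$seeds]
  graph$connected_counts <- counts[graph$seeds]
  graph$seed_threshold <- threshold
  graph
}

# internal: all patterns connected to a seed (children, related seeds and
# their children), excluding the seed itself
connected_patterns <- function(graph, seed) {
  setdiff(unique(c(graph$children[[seed]], graph$related[[seed]],
                   unlist(graph$children[graph$related[[seed]]],
                          use.names = FALSE))),
          seed)
}

#' Build a motif from a seed
#'
#' Anchors every pattern connected to the seed at its best PAM30 frame
#' against the seed (ties take the smallest offset), accumulates each
#' pattern's weight onto the residues it defines in each alignment column,
#' and includes residue `a` in a column when its weighted frequency is at
#' least `ratio_threshold` times its expected frequency AND the Poisson
#' exceedance of its weighted count (at rate total column weight times
#' expected frequency) is below `p_threshold`. Columns with no qualifying
#' residue become wildcards; all-wildcard margins are trimmed. A seed with
#' no connected patterns (or no qualifying column) yields the seed itself
#' as a singleton-column motif.
#'
#' @param seed Seed pattern notation.
#' @param graph A related `seed_graph` (after [relate_seeds()]).
#' @param weights Named numeric vector of positive pattern weights (typically
#'   each pattern's summed enrichment over the case samples, as stored in an
#'   `imune_scan`).
#' @param ratio_threshold Minimum observed/expected frequency ratio
#'   (default 1.5).
#' @param p_threshold Column-inclusion significance level (default 1e-4).
#' @param expected_profile Expected residue frequencies (default uniform).
#' @param matrix Substitution matrix.
#' @return An object of class `motif_candidate`: list with `motif`,
#'   `notation`, `source_seed`, `connected_pattern_count`,
#'   `contributing_seeds` (the seed and its related seeds) and
#'   `pattern_weights`.
#' @export
build_motif <- function(seed, graph, weights, ratio_threshold = 1.5,
                        p_threshold = 1e-4,
                        expected_profile = uniform_profile(),
                        matrix = pam30_matrix()) {
  stopifnot(inherits(graph, "seed_graph"), !is.null(graph$related))
  if (!seed %in% graph$seeds) stop("not a seed in this graph: ", seed)
  expected_profile <- as_profile(expected_profile)
  conn <- connected_patterns(graph, seed)
  members <- c(seed, conn)
  w <- weights[members]
  if (any(is.na(w)) || any(w <= 0)) stop("every member pattern needs a positive weight")

  offs <- integer(length(members))
  if (length(conn) > 0L) {
    offs[-1L] <- as.integer(cpp_align_best(seed, conn, matrix)$offset[1L, ])
  }
  spans <- nchar(members)
  # seed coordinate of each member's first column is offs + 1; lo re-bases to 1
  lo <- min(offs) + 1L
  ncol_aln <- max(offs + spans) - lo + 1L

  def_pos <- graph$def_pos[members]
  nres <- lengths(def_pos)
  aln_col <- unlist(def_pos, use.names = FALSE) +
    rep(offs - lo + 1L, nres)  # 1-based alignment column
  res_code <- match(unlist(graph$def_res[members], use.names = FALSE), AA20)
  wv <- rep(as.numeric(w), nres)

  W <- base::matrix(0, nrow = 20L, ncol = ncol_aln, dimnames = list(AA20, NULL))
  acc <- rowsum(wv, group = (aln_col - 1L) * 20L + res_code)
  key <- as.integer(rownames(acc))
  W[cbind((key - 1L) %% 20L + 1L, (key - 1L) %/% 20L + 1L)] <- acc[, 1L]

  # column frequencies are taken over the whole alignment (total member
  # weight), so a residue only qualifies when a substantial share of the
  # aligned patterns agrees on it -- sparsely covered columns cannot qualify
  total <- sum(w)
  lambda <- total * expected_profile
  columns <- vector("list", ncol_aln)
  for (j in seq_len(ncol_aln)) {
    freq <- W[, j] / total
    pcol <- poisson_tail_p_weighted(W[, j], lambda)
    ok <- freq >= ratio_threshold * expected_profile & pcol < p_threshold
    if (any(ok)) {
      res <- AA20[ok]
      columns[[j]] <- setNames(W[res, j], res)
    }
  }
  defined <- !vapply(columns, is.null, TRUE)
  if (!any(defined)) {
    m <- as_motif(seed)
  } else {
    first <- which(defined)[1L]
    last <- which(defined)[sum(defined)]
    m <- motif(columns[first:last])
  }
  structure(list(motif = m, notation = render_motif(m), source_seed = seed,
                 connected_pattern_count = length(conn),
                 child_count = length(graph$children[[seed]]),
                 contributing_seeds = c(seed, graph$related[[seed]]),
                 pattern_weights = setNames(as.numeric(w), members)),
            class = "motif_candidate")
}

#' @export
print.motif_candidate <- function(x, ...) {
  cat("motif_candidate ", x$notation, " (seed ", x$source_seed, ", ",
      x$connected_pattern_count, " connected patterns)\n", sep = "")
  invisible(x)
}

# internal: motif columns as bitmasks with 0 for wildcards (alignment-side
# representation, distinct from the all-bits wildcard used for matching)
scoring_masks <- function(m) {
  vapply(m$columns, function(col) {
    if (is.null(col)) return(0L)
    codes <- match(names(col), AA20) - 1L
    Reduce(bitwOr, bitwShiftL(1L, codes), 0L)
  }, 0L)
}

# internal: 0-based code of each column's most enriched residue (-1 wildcard)
top_residue_codes <- function(m) {
  vapply(m$columns, function(col) {
    if (is.null(col)) return(-1L)
    match(names(col)[order(-col, seq_along(col))][1L], AA20) - 1L
  }, 0L)
}

#' PAM30 alignment score between two motifs
#'
#' For every relative frame with at least one overlapping pair of defined
#' columns, each column pair scores the best of: the first motif's most
#' enriched residue against every residue of the second motif's column, and
#' vice versa. Wildcard pairings contribute 0. Returns the maximum frame
#' score (`-Inf` when no frame overlaps on defined columns).
#'
#' @param m1,m2 `imune_motif` objects (or notation strings; parsed columns
#'   get unit weights).
#' @param matrix Substitution matrix.
#' @return Integer score (or `-Inf`).
#' @export
motif_pair_score <- function(m1, m2, matrix = pam30_matrix()) {
  if (is.character(m1)) m1 <- parse_motif(m1)
  if (is.character(m2)) m2 <- parse_motif(m2)
  top_residue <- function(col) names(col)[order(-col, seq_along(col))][1L]
  c1 <- m1$columns; c2 <- m2$columns
  L1 <- length(c1); L2 <- length(c2)
  best <- -Inf
  for (off in seq.int(-(L2 - 1L), L1 - 1L)) {
    sc <- 0
    overlap <- FALSE
    for (j in seq_len(L2)) {
      i <- j + off
      if (i < 1L || i > L1) next
      if (is.null(c1[[i]]) || is.null(c2[[j]])) next
      overlap <- TRUE
      t1 <- top_residue(c1[[i]])
      t2 <- top_residue(c2[[j]])
      sc <- sc + max(max(matrix[t1, names(c2[[j]])]),
                     max(matrix[t2, names(c1[[i]])]))
    }
    if (overlap && sc > best) best <- sc
  }
  best
}

#' Merge related motifs and rank candidates
#'
#' Computes pairwise motif relatedness (alignment score at least
#' `threshold`) and re-orders the candidates by total pattern contributions:
#' a candidate's own connected-pattern count plus those of its related
#' candidates, descending, ties broken lexicographically by notation.
#'
#' @param candidates List of `motif_candidate` objects.
#' @param threshold Minimum motif alignment score for relatedness
#'   (default 10).
#' @param matrix Substitution matrix.
#' @return The candidates, re-ordered, each augmented with `related_motifs`
#'   (indices into the returned list are not stored; notations are) and
#'   `total_contributions`.
#' @export
merge_and_rank <- function(candidates, threshold = 10L, matrix = pam30_matrix()) {
  n <- length(candidates)
  if (n == 0L) return(candidates)
  notations <- vapply(candidates, `[[`, "", "notation")
  related <- vector("list", n)
  for (i in seq_len(n)) related[[i]] <- character(0)
  if (n > 1L) {
    masks <- lapply(candidates, function(cand) scoring_masks(cand$motif))
    tops <- lapply(candidates, function(cand) top_residue_codes(cand$motif))
    S <- cpp_motif_pair_scores(masks, tops, matrix)
    diag(S) <- -Inf
    adj <- is.finite(S) & S >= threshold
    for (i in seq_len(n)) related[[i]] <- notations[adj[i, ]]
  }
  counts <- vapply(candidates, `[[`, 0L, "connected_pattern_count")
  totals <- vapply(seq_len(n), function(i) {
    counts[i] + sum(counts[match(related[[i]], notations)])
  }, 0)
  for (i in seq_len(n)) {
    candidates[[i]]$related_motifs <- related[[i]]
    candidates[[i]]$total_contributions <- totals[i]
  }
  child_counts <- vapply(candidates, `[[`, 0L, "child_count")
  candidates[order(-totals, -child_counts, notations)]
}

#' Non-redundant motif list
#'
#' Walks the ranked candidates and keeps each motif whose source seed was
#' not already used in making a previously kept motif (a kept motif uses its
#' source seed and its related seeds).
#'
#' @param ranked Ranked list of `motif_candidate`s from [merge_and_rank()].
#' @return The kept candidates, order preserved.
#' @export
nonredundant_list <- function(ranked) {
  used <- character(0)
  keep <- logical(length(ranked))
  for (i in seq_along(ranked)) {
    if (!(ranked[[i]]$source_seed %in% used)) {
      keep[i] <- TRUE
      used <- union(used, ranked[[i]]$contributing_seeds)
    }
  }
  ranked[keep]
}

#' Leading distinct motif variants for a scoring panel
#'
#' Classification needs a small panel of motif variants (a primary and at
#' least one distinct secondary motif). This takes the full ranked motif
#' list produced by [cluster_patterns()] (kept in its `"redundant"`
#' attribute), drops duplicate notations and returns the first `n` motifs.
#'
#' @param motifs Result of [cluster_patterns()] (or any list of
#'   `motif_candidate`s).
#' @param n Maximum panel size (default 4).
#' @return List of `imune_motif` objects.
#' @export
motif_panel <- function(motifs, n = 4L) {
  ranked <- attr(motifs, "redundant")
  if (is.null(ranked)) ranked <- motifs
  uniq <- ranked[!duplicated(vapply(ranked, `[[`, "", "notation"))]
  lapply(utils::head(uniq, n), `[[`, "motif")
}

#' Cluster retained patterns into ranked motifs
#'
#' End-to-end clustering of a scan's retained patterns: seed graph,
#' PAM30 seed relatedness, per-seed motif construction weighted by summed
#' case enrichments, motif-level merging and the non-redundant list.
#'
#' @param scan An `imune_scan` with a non-empty retained set.
#' @param seed_threshold Seed relatedness score (default 5).
#' @param motif_threshold Motif relatedness score (default 10).
#' @param ratio_threshold,p_threshold Column inclusion rules (defaults 1.5
#'   and 1e-4).
#' @param expected_profile Expected residue frequencies for column
#'   statistics; defaults to the scan's mean effective-case profile.
#' @param matrix Substitution matrix.
#' @return List of `motif_candidate`s (the non-redundant ranked list), with
#'   the full ranked redundant list in attribute `"redundant"`.
#' @export
cluster_patterns <- function(scan, seed_threshold = 5L, motif_threshold = 10L,
                             ratio_threshold = 1.5, p_threshold = 1e-4,
                             expected_profile = NULL,
                             matrix = pam30_matrix()) {
  stopifnot(inherits(scan, "imune_scan"))
  if (length(scan$retained) == 0L) stop("scan retained no patterns")
  if (is.null(expected_profile)) expected_profile <- scan$case_profile
  graph <- build_seed_graph(scan$retained)
  graph <- relate_seeds(graph, threshold = seed_threshold, matrix = matrix)
  candidates <- lapply(graph$seeds, function(s) {
    build_motif(s, graph, scan$weights, ratio_threshold = ratio_threshold,
                p_threshold = p_threshold,
                expected_profile = expected_profile, matrix = matrix)
  })
  ranked <- merge_and_rank(candidates, threshold = motif_threshold, matrix = matrix)
  out <- nonredundant_list(ranked)
  attr(out, "redundant") <- ranked
  out
}
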