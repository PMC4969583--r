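# Independent oracles and small fixture builders shared across test files.

# Poisson exceedance by direct pmf summation in log space (independent of the
# package's pgamma/ppois route).
oracle_poisson_tail <- function(O, E, terms = 400L) {
  if (O == 0) return(1)
  j <- seq.int(O, O + terms)
  sum(exp(-E + j * log(E) - lgamma(j + 1)))
}

# Brute-force pattern enumeration: all strings over alphabet + 'x' filtered by
# the validity rules.
oracle_enumerate <- function(k_min, k_max, max_len, alphabet) {
  letters_x <- c(alphabet, "x")
  out <- character(0)
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(letters_x), L),
                      list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
    s <- do.call(paste0, grid)
    keep <- vapply(s, is_valid_pattern, TRUE,
                   k_min = k_min, k_max = k_max, max_len = max_len)
    out <- c(out, s[keep])
  }
  out
}

# Direct offset-scan of a pattern over one peptide using substring compares.
oracle_occurrences <- function(pattern, peptide) {
  pc <- strsplit(pattern, "")[[1]]
  pp <- strsplit(peptide, "")[[1]]
  L <- length(pc)
  defined <- which(pc != "x")
  hits <- 0L
  for (off in 0:(length(pp) - L)) {
    if (all(pp[off + defined] == pc[defined])) hits <- hits + 1L
  }
  hits
}

# Exhaustive rank-order selection by sweeping every threshold regime.
oracle_roc <- function(R_cases, R_controls, sens, spec) {
  vals <- sort(unique(c(R_cases, R_controls)))
  cands <- c(vals, vals + 1e-9, min(vals) - 1)
  for (t in cands) {
    if (mean(R_cases >= t) >= sens && mean(R_controls < t) >= spec) return(TRUE)
  }
  FALSE
}

# Exhaustive best-subset motif enrichment, all in plain R over a character
# matrix (independent of the C++ matcher).
oracle_top5 <- function(m, ps, n_positions = 5L) {
  if (is.character(m)) m <- parse_motif(m)
  cols <- m$columns
  defined <- which(!vapply(cols, is.null, TRUE))
  s <- min(n_positions, length(defined))
  pepmat <- do.call(rbind, strsplit(ps$peptides, ""))
  best <- -Inf
  best_sub <- NULL
  for (sub in combn(defined, s, simplify = FALSE)) {
    span <- max(sub) - min(sub) + 1L
    if (span > ps$peptide_length) next
    O <- 0L
    for (off in 0:(ps$peptide_length - span)) {
      ok <- rep(TRUE, nrow(pepmat))
      for (j in sub) {
        ok <- ok & pepmat[, off + j - min(sub) + 1L] %in% names(cols[[j]])
      }
      O <- O + sum(ok)
    }
    E <- ps$N * (ps$peptide_length - span + 1) *
      prod(vapply(cols[sub], function(cc) sum(ps$profile[names(cc)]), 0))
    R <- if (E > 0) O / E else 0
    if (R > best) { best <- R; best_sub <- sub }
  }
  list(enrichment = best, subset = best_sub)
}

# raw_reads built directly from vectors (bypasses file I/O).
make_reads <- function(peptides, counts = rep(1, length(peptides)),
                       sample_id = "test") {
  agg <- rowsum(counts, group = peptides)
  structure(list(sample_id = sample_id, peptides = rownames(agg),
                 counts = as.numeric(agg[, 1]),
                 rejected = c(length = 0L, alphabet = 0L)),
            class = "raw_reads")
}

# Uniform profile over a residue subset.
subset_profile <- function(residues) {
  setNames(ifelse(AA20 %in% residues, 1 / length(residues), 0), AA20)
}

# Random peptides over a restricted alphabet, unique.
random_peptides <- function(n, len = 12L, alphabet = AA20, seed = 1L) {
  withr::with_seed(seed, {
    peps <- character(0)
    while (length(peps) < n) {
      more <- replicate(n, paste(sample(alphabet, len, TRUE), collapse = ""))
      peps <- unique(c(peps, more))
    }
    peps[seq_len(n)]
  })
}

# The seven-residue study alphabet used by the planted-cohort fixtures.
study_alphabet <- function() c("Q", "P", "E", "F", "S", "W", "K")
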