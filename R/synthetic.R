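#' Generate a background peptide sample
#'
#' Draws `N` unique peptides with residues i.i.d. from a frequency profile,
#' rejection-resampling duplicates until the set is unique. Emulates the
#' non-redundant repertoires produced by display library screening (real
#' repertoires of this kind run to millions of unique 12-mers; desk-scale
#' values are appropriate for testing).
#'
#' @param N Number of unique peptides.
#' @param profile Residue frequency profile (default uniform).
#' @param peptide_length Default 12.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param sample_id Sample identifier.
#' @return A [peptide_set()].
#' @export
background_sample <- function(N, profile = uniform_profile(),
                              peptide_length = 12L, seed = NULL,
                              sample_id = "background") {
  profile <- as_profile(profile)
  n_res <- sum(profile > 0)
  if (log(N) > peptide_length * log(n_res))
    stop("N exceeds the number of distinct peptides the profile can produce")
  gen <- function() {
    peps <- character(0)
    while (length(peps) < N) {
      need <- N - length(peps)
      m <- matrix(sample(AA20, need * peptide_length, replace = TRUE,
                         prob = profile),
                  nrow = need)
      peps <- unique(c(peps, do.call(paste0, as.data.frame(m))))
    }
    peps[seq_len(N)]
  }
  peps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  peptide_set(sample_id, peps)
}

# internal: one random peptide realization containing the motif
realize_motif_peptide <- function(m, profile, peptide_length) {
  span <- motif_span(m)
  chars <- sample(AA20, peptide_length, replace = TRUE, prob = profile)
  off <- sample.int(peptide_length - span + 1L, 1L) - 1L
  for (j in seq_len(span)) {
    col <- m$columns[[j]]
    if (is.null(col)) next
    chars[off + j] <- sample(names(col), 1L)
  }
  paste(chars, collapse = "")
}

#' Plant motif-bearing peptides into a sample
#'
#' Replaces `ceiling(fraction * N)` randomly chosen peptides with peptides
#' containing one realization of the motif (bracket columns pick a residue
#' uniformly, flanks are drawn from the sample's profile, the offset is
#' uniform), keeping `N` fixed so enrichment effects are isolated from
#' library-size effects. The frequency profile is recomputed.
#'
#' @param ps A [peptide_set()].
#' @param m An `imune_motif` or notation string.
#' @param fraction Fraction of peptides to replace, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A new [peptide_set()] with the same `N`.
#' @export
plant_motif_peptides <- function(ps, m, fraction, seed = NULL) {
  stopifnot(inherits(ps, "peptide_set"))
  if (is.character(m)) m <- parse_motif(m)
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (motif_span(m) > ps$peptide_length) stop("motif span exceeds peptide length")
  if (fraction == 0) return(ps)
  n_plant <- as.integer(ceiling(fraction * ps$N))
  gen <- function() {
    peps <- ps$peptides
    drop <- sample.int(ps$N, n_plant)
    kept <- peps[-drop]
    planted <- character(0)
    while (length(planted) < n_plant) {
      cand <- vapply(seq_len(n_plant - length(planted)), function(i) {
        realize_motif_peptide(m, ps$profile, ps$peptide_length)
      }, "")
      planted <- unique(c(planted, setdiff(cand, kept)))
    }
    c(kept, planted[seq_len(n_plant)])
  }
  peps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  peptide_set(ps$sample_id, peps)
}

#' Specification of a synthetic cohort
#'
#' @param n_cases,n_controls Group sizes.
#' @param N_per_sample Unique peptides per sample.
#' @param peptide_length Default 12.
#' @param background_profile Background residue frequencies (default
#'   uniform).
#' @param plants List of plants, each a list with `motif` (notation),
#'   `case_fraction` and `control_fraction` (spike fractions in `[0, 1)`).
#' @param seed Integer master seed; every sample derives its own seed from
#'   it, so cohorts are fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, N_per_sample,
                        peptide_length = 12L,
                        background_profile = uniform_profile(),
                        plants = list(), seed = 1L) {
  for (pl in plants) {
    stopifnot(is.character(pl$motif),
              pl$case_fraction >= 0, pl$case_fraction < 1,
              pl$control_fraction >= 0, pl$control_fraction < 1)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 N_per_sample = N_per_sample, peptide_length = peptide_length,
                 background_profile = as_profile(background_profile),
                 plants = plants, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort in memory
#'
#' @param spec A [cohort_spec()].
#' @return List with `samples` (list of [peptide_set()]s, cases first) and
#'   `manifest` (data.frame: sample_id, group).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("case%02d", seq_len(spec$n_cases)),
           sprintf("control%02d", seq_len(spec$n_controls)))
  groups <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s_seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    ps <- background_sample(spec$N_per_sample, spec$background_profile,
                            spec$peptide_length, seed = s_seed,
                            sample_id = ids[i])
    for (k in seq_along(spec$plants)) {
      pl <- spec$plants[[k]]
      frac <- if (groups[i] == "case") pl$case_fraction else pl$control_fraction
      ps <- plant_motif_peptides(ps, pl$motif, frac,
                                 seed = (s_seed + 104729L * k) %% .Machine$integer.max)
    }
    samples[[i]] <- ps
  }
  list(samples = samples,
       manifest = data.frame(sample_id = ids, group = groups,
                             stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Writes one plain peptide list per sample plus `manifest.tsv`
#' (sample_id, path, group), reproducibly from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if absent).
#' @return The manifest data.frame, invisibly; the in-memory samples are in
#'   attribute `"samples"`.
#' @export
make_cohort <- function(spec, dir) {
  cohort <- simulate_cohort(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$manifest$sample_id, ".txt"))
  for (i in seq_along(cohort$samples)) {
    writeLines(cohort$samples[[i]]$peptides, paths[i])
  }
  manifest <- data.frame(sample_id = cohort$manifest$sample_id,
                         path = paths, group = cohort$manifest$group,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(manifest, "samples") <- cohort$samples
  invisible(manifest)
}

#' Read a cohort manifest and its peptide lists
#'
#' @param manifest_path Path to a `manifest.tsv` with columns `sample_id`,
#'   `path`, `group` (relative paths resolve against the manifest's
#'   directory).
#' @param expected_length Peptide length (default 12).
#' @return List with `samples` (list of [peptide_set()]s) and `manifest`.
#' @export
read_cohort <- function(manifest_path, expected_length = 12L) {
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    reads <- read_sample_peptides(p, "plain", expected_length,
                                  sample_id = manifest$sample_id[i])
    build_nonredundant_set(reads, max_mutations = 0L)
  })
  list(samples = samples, manifest = manifest)
}
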