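#' Run configuration for a cohort scan
#'
#' The five standard run modes map onto the three selection methods:
#' \describe{
#'   \item{i}{Poisson method; significant in the case group, non-significant
#'     in every control.}
#'   \item{ii}{Standard-deviation method; cases at least `sd_multiplier`
#'     standard deviations above the control mean.}
#'   \item{iii}{As mode i with the group roles swapped (control-enriched
#'     patterns).}
#'   \item{iv}{As mode ii with the group roles swapped.}
#'   \item{v}{Poisson method on the combined cohort (default sensitivity
#'     fraction 0.8) with no non-significance condition.}
#' }
#'
#' @param mode One of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`.
#' @param cases,controls Character vectors of sample ids.
#' @param criterion Optional [selection_criterion()]; a mode-appropriate
#'   default is built when `NULL`.
#' @param pattern_bounds Integer vector `c(k_min, k_max, max_len)`
#'   (default `c(3, 5, 10)`).
#' @param restriction Optional character vector of residues; the scan is
#'   limited to patterns whose defined residues all belong to this set
#'   (a desk-scale hook -- expected observations still use the full sample
#'   profile).
#' @param shards Number of deterministic first-residue shards to process the
#'   pattern space in (default 1); sharding bounds the per-pass accumulator
#'   memory and yields identical results.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("i", "ii", "iii", "iv", "v"),
                       cases, controls = character(0), criterion = NULL,
                       pattern_bounds = c(3L, 5L, 10L),
                       restriction = NULL, shards = 1L) {
  mode <- match.arg(mode)
  if (length(cases) == 0L) stop("case group must be non-empty")
  if (mode != "v" && length(controls) == 0L)
    stop("control group must be non-empty for modes i-iv")
  if (length(intersect(cases, controls)) > 0L)
    stop("case and control groups must be disjoint")
  if (length(pattern_bounds) != 3L || pattern_bounds[1] > pattern_bounds[2] ||
      pattern_bounds[2] > pattern_bounds[3])
    stop("pattern_bounds must be c(k_min, k_max, max_len) with k_min <= k_max <= max_len")
  if (!is.null(restriction) && !all(restriction %in% AA20))
    stop("restriction must name standard amino acids")
  if (is.null(criterion)) {
    criterion <- switch(mode,
      i = selection_criterion("poisson"),
      ii = selection_criterion("stddev"),
      iii = selection_criterion("poisson"),
      iv = selection_criterion("stddev"),
      v = selection_criterion("poisson", sensitivity_fraction = 0.8))
  }
  structure(list(mode = mode, cases = cases, controls = controls,
                 criterion = criterion,
                 pattern_bounds = as.integer(pattern_bounds),
                 restriction = restriction, shards = as.integer(shards)),
            class = "run_config")
}

# internal: effective case/control ids after applying the mode's role swap
effective_groups <- function(config) {
  switch(config$mode,
    i = ,
    ii = list(cases = config$cases, controls = config$controls),
    iii = ,
    iv = list(cases = config$controls, controls = config$cases),
    v = list(cases = c(config$cases, config$controls), controls = character(0)))
}

#' Count every pattern in one sample
#'
#' Exhaustively counts offset matches of all patterns within the bounds by
#' emitting, for every peptide, each of its contained (layout, residues)
#' sub-pattern instances into a hash accumulator. Work therefore scales with
#' the number of peptides times the instances per peptide (1,074 for 12-mers
#' at the default bounds), not with the 4.2e8-strong pattern space.
#'
#' @param ps A [peptide_set()].
#' @param pattern_bounds `c(k_min, k_max, max_len)`.
#' @param restriction Optional residue subset; only patterns made of these
#'   residues are counted.
#' @param first_residues Optional residue subset constraining the first
#'   defined position (the sharding hook).
#' @param keys_only Keep the internal packed pattern keys instead of
#'   materializing notation strings (used by [scan_cohort()] to keep
#'   per-sample tables light).
#' @return A [data.table::data.table] with columns `pattern` (notation;
#'   `key` when `keys_only`), `O` (observed count), `L`, `k` and `prod_f`
#'   (product of this sample's residue frequencies over the pattern's
#'   defined positions). Patterns with zero observations are omitted
#'   (implicitly zero).
#' @export
count_patterns_in_sample <- function(ps, pattern_bounds = c(3L, 5L, 10L),
                                     restriction = NULL, first_residues = NULL,
                                     keys_only = FALSE) {
  stopifnot(inherits(ps, "peptide_set"))
  layouts <- pattern_layouts(pattern_bounds[1], pattern_bounds[2], pattern_bounds[3])
  allowed <- if (is.null(restriction)) rep(TRUE, 20L) else AA20 %in% restriction
  first <- if (is.null(first_residues)) allowed else allowed & (AA20 %in% first_residues)
  df <- cpp_count_subpatterns(ps$peptides, layouts, allowed, first, ps$profile)
  dt <- data.table::as.data.table(df)
  if (keys_only) {
    data.table::setkeyv(dt, "key")
  } else {
    dt[, "pattern" := cpp_keys_to_patterns(dt$key, layouts)]
    dt[, "key" := NULL]
    data.table::setcolorder(dt, "pattern")
    data.table::setkeyv(dt, "pattern")
  }
  dt
}

#' Scan a cohort for significant patterns
#'
#' Counts every pattern within the configured bounds in every sample,
#' computes per-sample observed/expected counts, enrichments and Poisson
#' tail probabilities (each sample using its own N and frequency profile),
#' and retains the patterns satisfying the run mode's selection criterion.
#'
#' Candidate patterns are restricted to those observed (for the Poisson
#' method: significant) in at least the required number of effective case
#' samples; this prefilter is exact, because every criterion needs a
#' positive enrichment in that many case samples.
#'
#' @param samples List of [peptide_set()] objects covering all configured
#'   sample ids.
#' @param config A [run_config()].
#' @return An object of class `imune_scan` with elements `retained`
#'   (pattern notation vector), `stats` (long data.table: pattern, sample_id,
#'   group, O, E, R, p for retained patterns), `weights` (per-pattern summed
#'   enrichment over the effective case samples, the clustering weight),
#'   `samples` (sample metadata), `case_profile` (mean effective-case
#'   profile) and `config`. An empty retained set is a valid outcome.
#' @export
scan_cohort <- function(samples, config) {
  stopifnot(inherits(config, "run_config"))
  ids <- vapply(samples, function(s) s$sample_id, "")
  names(samples) <- ids
  groups <- effective_groups(config)
  need <- c(groups$cases, groups$controls)
  missing <- setdiff(need, ids)
  if (length(missing) > 0L)
    stop("samples missing from cohort: ", paste(missing, collapse = ", "))
  samples <- samples[need]

  shard_sets <- shard_first_residues(config)
  parts <- lapply(shard_sets, function(fr) {
    scan_shard(samples, config, groups, first_residues = fr)
  })
  stats <- data.table::rbindlist(lapply(parts, `[[`, "stats"))
  retained <- unlist(lapply(parts, `[[`, "retained"), use.names = FALSE)
  ord <- order(retained)
  retained <- retained[ord]
  if (nrow(stats) > 0L) data.table::setorderv(stats, c("pattern", "sample_id"))

  weights <- numeric(0)
  if (length(retained) > 0L) {
    case_stats <- stats[stats$sample_id %in% groups$cases, ]
    w <- case_stats[, list(w = sum(R)), by = "pattern"]
    weights <- setNames(w$w, w$pattern)[retained]
  }

  meta <- data.table::data.table(
    sample_id = need,
    N = vapply(samples, function(s) s$N, 0),
    group = c(rep("case", length(groups$cases)),
              rep("control", length(groups$controls))))
  case_profile <- as_profile(
    rowMeans(vapply(samples[groups$cases], function(s) s$profile, numeric(20L))))

  structure(list(retained = retained, stats = stats, weights = weights,
                 samples = meta, case_profile = case_profile, config = config),
            class = "imune_scan")
}

# internal: residue sets for the first defined position, one per shard
shard_first_residues <- function(config) {
  allowed <- if (is.null(config$restriction)) AA20 else
    AA20[AA20 %in% config$restriction]
  n <- max(1L, min(config$shards, length(allowed)))
  split(allowed, rep(seq_len(n), length.out = length(allowed)))
}

# internal: full selection logic for one first-residue shard
scan_shard <- function(samples, config, groups, first_residues) {
  crit <- config$criterion
  method <- crit$method
  pl <- samples[[1]]$peptide_length
  n_case <- length(groups$cases)
  k_req <- required_count(crit$sensitivity_fraction, n_case)

  tabs <- lapply(samples, function(ps) {
    count_patterns_in_sample(ps, config$pattern_bounds,
                             restriction = config$restriction,
                             first_residues = first_residues,
                             keys_only = TRUE)
  })

  # candidate prefilter over effective case samples (packed keys)
  cand_lists <- lapply(groups$cases, function(id) {
    dt <- tabs[[id]]
    if (nrow(dt) == 0L) return(numeric(0))
    if (method == "poisson") {
      E <- samples[[id]]$N * (pl - dt$L + 1) * dt$prod_f
      dt$key[poisson_tail_p(dt$O, E) < crit$p_sig]
    } else {
      dt$key
    }
  })
  tally <- data.table::data.table(pkey = unlist(cand_lists, use.names = FALSE))
  tally <- tally[, list(n = .N), by = "pkey"]
  cand_keys <- sort(tally$pkey[tally$n >= k_req])
  empty <- list(retained = character(0),
                stats = data.table::data.table(
                  pattern = character(0), sample_id = character(0),
                  group = character(0), O = numeric(0), E = numeric(0),
                  R = numeric(0), p = numeric(0)))
  if (length(cand_keys) == 0L) return(empty)

  layouts <- pattern_layouts(config$pattern_bounds[1], config$pattern_bounds[2],
                             config$pattern_bounds[3])
  cand <- cpp_keys_to_patterns(cand_keys, layouts)
  Lc <- nchar(cand)
  res <- gsub("x", "", cand, fixed = TRUE)
  all_ids <- c(groups$cases, groups$controls)
  nO <- length(cand)
  O <- E <- matrix(0, nrow = nO, ncol = length(all_ids),
                   dimnames = list(cand, all_ids))
  for (id in all_ids) {
    ps <- samples[[id]]
    dt <- tabs[[id]]
    idx <- match(cand_keys, dt$key)
    O[, id] <- ifelse(is.na(idx), 0, dt$O[idx])
    E[, id] <- ps$N * (pl - Lc + 1) * cpp_profile_products(res, ps$profile)
  }
  R <- O / E
  P <- matrix(poisson_tail_p(as.vector(O), as.vector(E)),
              nrow = nO, dimnames = dimnames(O))

  ci <- groups$cases
  keep <- switch(method,
    poisson = {
      ok_case <- rowSums(P[, ci, drop = FALSE] < crit$p_sig) >= k_req
      if (length(groups$controls) == 0L) ok_case else {
        k_ctl <- required_count(crit$specificity_fraction, length(groups$controls))
        ok_case &
          rowSums(P[, groups$controls, drop = FALSE] > crit$p_nonsig) >= k_ctl
      }
    },
    stddev = {
      if (length(groups$controls) < 2L) stop("need at least two control samples")
      Rc <- R[, groups$controls, drop = FALSE]
      mu <- rowMeans(Rc)
      nctl <- ncol(Rc)
      sdev <- sqrt(pmax(rowSums((Rc - mu)^2) / (nctl - 1), 0))
      thr <- mu + crit$sd_multiplier * pmax(sdev, crit$sd_floor)
      rowSums(R[, ci, drop = FALSE] >= thr) >= k_req
    },
    roc = {
      if (length(groups$controls) == 0L) stop("empty control group")
      apply_roc(R, ci, groups$controls, crit)
    })
  # zero-frequency residues give E = 0 (undefined enrichment); such patterns
  # cannot be observed there and are excluded from selection
  keep <- keep & rowSums(E <= 0) == 0L

  retained <- cand[keep]
  if (length(retained) == 0L) return(empty)
  stats <- data.table::data.table(
    pattern = rep(retained, times = length(all_ids)),
    sample_id = rep(all_ids, each = length(retained)),
    group = rep(c(rep("case", length(ci)),
                  rep("control", length(groups$controls))),
                each = length(retained)),
    O = as.vector(O[keep, , drop = FALSE]),
    E = as.vector(E[keep, , drop = FALSE]),
    R = as.vector(R[keep, , drop = FALSE]),
    p = as.vector(P[keep, , drop = FALSE]))
  list(retained = retained, stats = stats)
}

# internal: vectorized rank-order selection over a candidate matrix
apply_roc <- function(R, case_ids, control_ids, crit) {
  k_case <- required_count(crit$sensitivity_fraction, length(case_ids))
  k_ctl <- required_count(crit$specificity_fraction, length(control_ids))
  Rc <- R[, case_ids, drop = FALSE]
  Rk <- R[, control_ids, drop = FALSE]
  q_case <- apply(Rc, 1L, function(x) sort(x, decreasing = TRUE)[k_case])
  c_star <- apply(Rk, 1L, function(x) {
    sort(x, decreasing = TRUE)[length(x) - k_ctl + 1L]
  })
  q_case > c_star
}

#' @export
print.imune_scan <- function(x, ...) {
  cat("imune_scan (mode ", x$config$mode, "): ", length(x$retained),
      " retained patterns over ", nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Export and re-import a retained-pattern table
#'
#' Writes one row per retained pattern with its selection flag and the four
#' per-sample statistics (`O_<id>`, `E_<id>`, `R_<id>`, `p_<id>`), as TSV.
#'
#' @param scan An `imune_scan`.
#' @param path Output TSV path.
#' @return The wide [data.table::data.table] that was written, invisibly.
#' @export
export_pattern_table <- function(scan, path) {
  stopifnot(inherits(scan, "imune_scan"))
  ids <- scan$samples$sample_id
  wide <- data.table::data.table(pattern = scan$retained, selected = TRUE)
  for (id in ids) {
    sub <- scan$stats[scan$stats$sample_id == id, ]
    idx <- match(scan$retained, sub$pattern)
    wide[[paste0("O_", id)]] <- sub$O[idx]
    wide[[paste0("E_", id)]] <- sub$E[idx]
    wide[[paste0("R_", id)]] <- sub$R[idx]
    wide[[paste0("p_", id)]] <- sub$p[idx]
  }
  data.table::fwrite(wide, path, sep = "\t")
  invisible(wide)
}

#' @rdname export_pattern_table
#' @export
read_pattern_table <- function(path) {
  data.table::fread(path, sep = "\t")
}
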