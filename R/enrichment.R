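#' Expected observations of a pattern or motif
#'
#' Under the independence assumption, the expected number of offset matches
#' of a pattern (or motif) in a sample of `N` unique peptides of length
#' `peptide_length` is
#' `N * (peptide_length - L + 1) * prod over defined columns of sum(f(a))`,
#' where the sum runs over the residues allowed in that column and `f` is the
#' sample's amino-acid frequency profile. Wildcard columns contribute a
#' factor of 1.
#'
#' @param x Pattern notation string or `imune_motif` (bracketed notation
#'   strings are also accepted).
#' @param profile Amino-acid frequency profile (named numeric over [AA20]).
#' @param N Number of unique peptides in the sample.
#' @param peptide_length Peptide length (default 12).
#' @return Expected observation count (non-negative real).
#' @examples
#' expected_observations("AAA", setNames(c(1, rep(0, 19)), AA20), 10)  # 100
#' @export
expected_observations <- function(x, profile, N, peptide_length = 12L) {
  if (N <= 0) stop("N must be positive")
  profile <- as_profile(profile)
  m <- if (inherits(x, "imune_motif")) x else parse_motif(x)
  L <- motif_span(m)
  if (L > peptide_length) stop("pattern span exceeds peptide length")
  fac <- vapply(m$columns, function(col) {
    if (is.null(col)) 1 else sum(profile[names(col)])
  }, 0)
  N * (peptide_length - L + 1) * prod(fac)
}

#' Enrichment ratio
#'
#' Ratio of actual to expected observations.
#'
#' @param O Observed count (non-negative).
#' @param E Expected count (must be positive).
#' @return `O / E`.
#' @export
enrichment_ratio <- function(O, E) {
  if (any(E <= 0)) stop("expected observations must be positive")
  O / E
}

#' Poisson exceedance probability
#'
#' One-sided tail probability `P(X >= O)` for `X ~ Poisson(E)`, computed via
#' the regularized incomplete gamma function (numerically stable in the far
#' tail). The tail includes the observed count, so `O = 0` gives `p = 1`.
#'
#' @param O Observed count(s), non-negative.
#' @param E Expected count(s), positive.
#' @return Tail probability in `[0, 1]`; vectorized over `O` and `E`.
#' @examples
#' poisson_tail_p(1, 1)  # 1 - exp(-1)
#' @export
poisson_tail_p <- function(O, E) {
  if (any(O < 0)) stop("observed counts must be non-negative")
  if (any(E <= 0)) stop("expected counts must be positive")
  ppois(O - 1, E, lower.tail = FALSE)
}

# internal: continuous-weight analogue used for motif column statistics;
# P(X >= w) for X ~ Poisson(lambda) extended to real w via pgamma
poisson_tail_p_weighted <- function(w, lambda) {
  ifelse(w <= 0, 1, pgamma(lambda, shape = w, lower.tail = TRUE))
}

#' Pattern selection criterion
#'
#' Bundles the thresholds of the three selection methods. `p_sig` and
#' `p_nonsig` bound the Poisson method (`p < p_sig` in a sufficient fraction
#' of cases, `p > p_nonsig` in a sufficient fraction of controls; the default
#' 0.0313 corresponds to a 50% family-wise chance over 16 case samples,
#' 0.50 / 16). `sd_multiplier` sets the standard-deviation method's threshold
#' above the control mean, with `sd_floor` guarding zero-variance controls.
#' Required fractions are converted to counts by rounding up.
#'
#' @param method `"poisson"`, `"stddev"` or `"roc"`.
#' @param p_sig Case significance level (default 1e-4).
#' @param p_nonsig Control non-significance level (default 0.0313).
#' @param sd_multiplier Standard deviations above the control mean (default 4).
#' @param sensitivity_fraction Required fraction of case samples (default 0.5).
#' @param specificity_fraction Required fraction of control samples (default 1).
#' @param sd_floor Lower bound on the control standard deviation, in
#'   enrichment units (default 0.01).
#' @return An object of class `selection_criterion`.
#' @export
selection_criterion <- function(method = c("poisson", "stddev", "roc"),
                                p_sig = 1e-4, p_nonsig = 0.0313,
                                sd_multiplier = 4,
                                sensitivity_fraction = 0.5,
                                specificity_fraction = 1.0,
                                sd_floor = 0.01) {
  method <- match.arg(method)
  if (!(p_sig > 0 && p_sig < p_nonsig && p_nonsig < 1))
    stop("need 0 < p_sig < p_nonsig < 1")
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive")
  if (sensitivity_fraction <= 0 || sensitivity_fraction > 1 ||
      specificity_fraction <= 0 || specificity_fraction > 1)
    stop("fractions must lie in (0, 1]")
  structure(list(method = method, p_sig = p_sig, p_nonsig = p_nonsig,
                 sd_multiplier = sd_multiplier,
                 sensitivity_fraction = sensitivity_fraction,
                 specificity_fraction = specificity_fraction,
                 sd_floor = sd_floor),
            class = "selection_criterion")
}

# internal: "at least fraction of n" as a count, rounded up
required_count <- function(fraction, n) as.integer(ceiling(fraction * n))

#' Poisson selection
#'
#' Retains a pattern when its Poisson tail probability is below `p_sig` in at
#' least `sensitivity_fraction` of case samples and above `p_nonsig` in at
#' least `specificity_fraction` of control samples. An empty control vector
#' drops the non-significance condition (used by the combined-group run mode,
#' which states no control condition).
#'
#' @param p_cases,p_controls Per-sample tail probabilities.
#' @param criterion A [selection_criterion()].
#' @return `TRUE` or `FALSE`.
#' @export
select_poisson <- function(p_cases, p_controls, criterion = selection_criterion()) {
  if (length(p_cases) == 0L) stop("empty case group")
  ok_cases <- sum(p_cases < criterion$p_sig) >=
    required_count(criterion$sensitivity_fraction, length(p_cases))
  ok_controls <- length(p_controls) == 0L ||
    sum(p_controls > criterion$p_nonsig) >=
      required_count(criterion$specificity_fraction, length(p_controls))
  ok_cases && ok_controls
}

#' Standard-deviation selection
#'
#' Retains a pattern when its enrichment exceeds
#' `mean(controls) + sd_multiplier * sd(controls)` in at least
#' `sensitivity_fraction` of case samples. The control standard deviation is
#' the sample (n - 1) estimator, floored at `sd_floor`.
#'
#' @param R_cases,R_controls Per-sample enrichment ratios.
#' @param criterion A [selection_criterion()].
#' @return `TRUE` or `FALSE`.
#' @export
select_stddev <- function(R_cases, R_controls, criterion = selection_criterion("stddev")) {
  if (length(R_cases) == 0L) stop("empty case group")
  if (length(R_controls) < 2L) stop("need at least two control samples")
  s <- max(sd(R_controls), criterion$sd_floor)
  threshold <- mean(R_controls) + criterion$sd_multiplier * s
  sum(R_cases >= threshold) >=
    required_count(criterion$sensitivity_fraction, length(R_cases))
}

#' Rank-order (ROC) selection
#'
#' Retains a pattern when some enrichment threshold t simultaneously attains
#' the required sensitivity (fraction of cases with `R >= t`) and specificity
#' (fraction of controls with `R < t`). Ties between groups require a strict
#' separator: such a threshold exists exactly when the case value achieving
#' the required sensitivity strictly exceeds the control value that must be
#' excluded.
#'
#' @param R_cases,R_controls Per-sample enrichment ratios.
#' @param criterion A [selection_criterion()].
#' @return `TRUE` or `FALSE`.
#' @export
select_roc <- function(R_cases, R_controls, criterion = selection_criterion("roc")) {
  if (length(R_cases) == 0L || length(R_controls) == 0L) stop("empty group")
  n_case <- length(R_cases)
  n_ctl <- length(R_controls)
  k_case <- required_count(criterion$sensitivity_fraction, n_case)
  k_ctl <- required_count(criterion$specificity_fraction, n_ctl)
  # k_case-th largest case value: sensitivity holds for any t <= this value
  q_case <- sort(R_cases, decreasing = TRUE)[k_case]
  # at most n_ctl - k_ctl controls may sit at or above t, so t must strictly
  # exceed the (n_ctl - k_ctl + 1)-th largest control value
  c_star <- sort(R_controls, decreasing = TRUE)[n_ctl - k_ctl + 1L]
  q_case > c_star
}
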