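test_that("single-peptide counting finds exactly the contained patterns", {
  tab <- count_patterns_in_sample(peptide_set("t", "AAAAAAAAAAAA"), c(3, 3, 3))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$pattern, "AAA")
  expect_equal(tab$O, 10)
})

test_that("every 12-mer emits 1,074 sub-pattern instances at default bounds", {
  # sum over spans of (offsets) x (layouts): derived independently here
  layouts_per_span <- vapply(3:10, function(L) {
    sum(vapply(3:5, function(k) if (k > L) 0 else choose(L - 2, k - 2), 0))
  }, 0)
  per_peptide <- sum((13 - (3:10)) * layouts_per_span)
  expect_equal(per_peptide, 1074)
  ps <- peptide_set("t", random_peptides(40, seed = 12))
  tab <- count_patterns_in_sample(ps)
  expect_equal(sum(tab$O), 1074 * 40)
})

test_that("emission counting equals per-pattern matching on small alphabets", {
  acd <- c("A", "C", "D")
  ps <- peptide_set("t", random_peptides(50, alphabet = acd, seed = 13))
  tab <- count_patterns_in_sample(ps, c(3, 3, 5))
  all_pats <- enumerate_patterns(3, 3, 5, acd)
  direct <- vapply(all_pats, function(p) {
    sum(vapply(ps$peptides, function(pep) oracle_occurrences(p, pep), 0L))
  }, 0)
  direct <- direct[direct > 0]
  expect_equal(sort(names(direct)), sort(tab$pattern))
  expect_equal(direct[tab$pattern], setNames(tab$O, tab$pattern))
})

test_that("counting is additive over disjoint peptide sets", {
  p1 <- "ACDEFGHIKLMN"
  p2 <- "PQRSTVWYACDE"
  t1 <- count_patterns_in_sample(peptide_set("a", p1), c(3, 4, 6))
  t2 <- count_patterns_in_sample(peptide_set("b", p2), c(3, 4, 6))
  t12 <- count_patterns_in_sample(peptide_set("ab", c(p1, p2)), c(3, 4, 6))
  merged <- rbind(t1[, c("pattern", "O")], t2[, c("pattern", "O")])
  merged <- merged[, list(O = sum(O)), by = "pattern"]
  expect_equal(sum(t12$O), sum(merged$O))
  expect_equal(setNames(t12$O, t12$pattern)[merged$pattern],
               setNames(merged$O, merged$pattern))
})

test_that("alphabet restriction filters rather than recounts", {
  ps <- peptide_set("t", random_peptides(30, seed = 14))
  full <- count_patterns_in_sample(ps, c(3, 3, 5))
  restr <- count_patterns_in_sample(ps, c(3, 3, 5),
                                    restriction = c("A", "C", "D", "E"))
  keep <- grepl("^[ACDEx]+$", full$pattern)
  expect_equal(sort(restr$pattern), sort(full$pattern[keep]))
  # dense small-alphabet accumulator and hash path agree
  both <- merge(restr, full[keep, ], by = "pattern")
  expect_equal(both$O.x, both$O.y)
  expect_equal(both$prod_f.x, both$prod_f.y)
})

test_that("scanning identical case and control groups retains nothing", {
  alpha <- study_alphabet()
  sets <- lapply(1:3, function(i) {
    peptide_set(paste0("s", i), random_peptides(300, alphabet = alpha, seed = i))
  })
  cases <- lapply(sets, function(s) { s$sample_id <- paste0(s$sample_id, "_case"); s })
  controls <- lapply(sets, function(s) { s$sample_id <- paste0(s$sample_id, "_ctl"); s })
  cfg <- run_config("i", cases = vapply(cases, `[[`, "", "sample_id"),
                    controls = vapply(controls, `[[`, "", "sample_id"),
                    restriction = alpha)
  scan <- scan_cohort(c(cases, controls), cfg)
  expect_length(scan$retained, 0L)
  # and an empty retained set exports as a header-only table
  f <- withr::local_tempfile(fileext = ".tsv")
  export_pattern_table(scan, f)
  expect_equal(nrow(read_pattern_table(f)), 0L)
})

local({
  # one small planted cohort shared by the scan behaviour tests
  alpha <- study_alphabet()
  spec <- cohort_spec(4, 4, 5000, background_profile = subset_profile(alpha),
                      plants = list(list(motif = "QPEQPF[PS]E",
                                         case_fraction = 0.01,
                                         control_fraction = 0)),
                      seed = 77)
  coh <- simulate_cohort(spec)
  ids_case <- sprintf("case%02d", 1:4)
  ids_ctl <- sprintf("control%02d", 1:4)

  test_that("mode-i scans recover planted sub-patterns", {
    cfg <- run_config("i", cases = ids_case, controls = ids_ctl, restriction = alpha)
    scan <- scan_cohort(coh$samples, cfg)
    expect_gt(length(scan$retained), 0L)
    expect_true(all(c("QPE", "EQP", "QPEQP") %in% scan$retained))
    expect_true(all(scan$weights > 0))
    # retained stats cover every sample for every retained pattern
    expect_equal(nrow(scan$stats), length(scan$retained) * 8L)
    expect_equal(scan$stats$R, scan$stats$O / scan$stats$E)

    # runs i and ii retain overlapping sets
    cfg2 <- run_config("ii", cases = ids_case, controls = ids_ctl, restriction = alpha)
    scan2 <- scan_cohort(coh$samples, cfg2)
    common <- intersect(scan$retained, scan2$retained)
    expect_gt(length(common), 0L)

    # sharding the pattern space changes nothing
    cfg3 <- run_config("i", cases = ids_case, controls = ids_ctl,
                       restriction = alpha, shards = 3)
    scan3 <- scan_cohort(coh$samples, cfg3)
    expect_identical(scan3$retained, scan$retained)
    expect_equal(scan3$weights, scan$weights)

    # role-swapped mode iii on this cohort finds no control-enriched patterns
    cfg4 <- run_config("iii", cases = ids_case, controls = ids_ctl, restriction = alpha)
    expect_length(scan_cohort(coh$samples, cfg4)$retained, 0L)

    # pattern tables round-trip through TSV
    f <- withr::local_tempfile(fileext = ".tsv")
    wide <- export_pattern_table(scan, f)
    back <- read_pattern_table(f)
    expect_equal(ncol(wide), 2L + 4L * 8L)
    expect_equal(names(back), names(wide))
    expect_equal(back$pattern, wide$pattern)
    for (cn in setdiff(names(wide), c("pattern", "selected"))) {
      expect_equal(as.numeric(back[[cn]]), as.numeric(wide[[cn]]))
    }
  })

  test_that("mode v applies the combined-group rule without controls", {
    cfgv <- run_config("v", cases = ids_case, controls = ids_ctl, restriction = alpha)
    scanv <- scan_cohort(coh$samples, cfgv)
    # planted patterns sit in only half the combined cohort, below the 80%
    # sensitivity bar, so mode v retains none of them
    expect_false(any(c("QPE", "QPEQP") %in% scanv$retained))
  })
})

test_that("scan configuration is validated", {
  expect_error(run_config("i", cases = character(0), controls = "c1"))
  expect_error(run_config("i", cases = "a", controls = "a"))
  expect_error(run_config("i", cases = "a", controls = "b",
                          pattern_bounds = c(5, 3, 10)))
  cfg <- run_config("i", cases = "a", controls = "b")
  ps <- peptide_set("a", "AAAAAAAAAAAA")
  expect_error(scan_cohort(list(ps), cfg), "missing")
})
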