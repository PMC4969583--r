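pam <- pam30_matrix()

test_that("the PAM30 matrix covers the 20 residues symmetrically", {
  expect_equal(dim(pam), c(20L, 20L))
  expect_identical(rownames(pam), AA20)
  expect_true(isSymmetric(unname(pam)))
})

test_that("seed graphs reproduce the worked parent/child structure", {
  g <- build_seed_graph(c("PEQP", "PEQxxP", "PEQPxP"))
  expect_setequal(g$seeds, c("PEQP", "PEQxxP"))
  expect_equal(sort(g$children[["PEQP"]]), "PEQPxP")
  expect_equal(sort(g$children[["PEQxxP"]]), "PEQPxP")

  g1 <- build_seed_graph("QPE")
  expect_equal(g1$seeds, "QPE")
  expect_length(g1$children[["QPE"]], 0L)

  g2 <- build_seed_graph(c("ACD", "ACDxD"))
  expect_equal(g2$seeds, "ACD")
  expect_equal(g2$children[["ACD"]], "ACDxD")
})

test_that("pattern alignment scores defined overlaps only", {
  self <- align_pattern_pair("PEQ", "PEQ", pam)
  expect_equal(self$score, pam["P", "P"] + pam["E", "E"] + pam["Q", "Q"])
  expect_equal(self$offset, 0L)
  # wildcard columns contribute nothing
  wc <- align_pattern_pair("AxA", "AAA", pam)
  expect_equal(wc$score, 2 * pam["A", "A"])
  expect_equal(wc$offset, 0L)
  # dissimilar residues settle for the least-bad frame; exhaustive frame
  # sweep written out directly as the oracle
  frame_scores <- vapply(-2:2, function(off) {
    a <- c("P", "E", "Q"); b <- c("W", "W", "W")
    js <- seq_len(3); ia <- js + off
    ok <- ia >= 1 & ia <= 3
    if (!any(ok)) return(NA_real_)
    sum(pam[cbind(a[ia[ok]], b[js[ok]])])
  }, 0)
  ww <- align_pattern_pair("PEQ", "WWW", pam)
  expect_equal(ww$score, max(frame_scores, na.rm = TRUE))
})

test_that("scalar and bulk aligners agree, and scores are symmetric", {
  pats <- withr::with_seed(51, sample(enumerate_patterns(3, 4, 7, c("A", "C", "W", "P")), 12))
  bulk <- imune:::cpp_align_best(pats, pats, pam)
  for (i in seq_along(pats)) {
    for (j in seq_along(pats)) {
      ref <- align_pattern_pair(pats[i], pats[j], pam)
      expect_equal(bulk$score[i, j], ref$score)
      expect_equal(bulk$offset[i, j], ref$offset)
      expect_equal(ref$score, align_pattern_pair(pats[j], pats[i], pam)$score)
    }
  }
})

test_that("seed relatedness applies the threshold at the best frame", {
  # toy matrix isolates the boundary: diagonal 2, off-diagonal 0
  toy <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  diag(toy) <- 2L
  g <- build_seed_graph(c("ACA", "ACC", "AWW"))
  g5 <- relate_seeds(g, threshold = 5, matrix = toy)
  # ACA vs ACC share AC -> score 4 < 5; not related
  expect_length(g5$related[["ACA"]], 0L)
  g4 <- relate_seeds(g, threshold = 4, matrix = toy)
  expect_equal(g4$related[["ACA"]], "ACC")
  expect_equal(g4$related[["ACC"]], "ACA")
  # identical seeds cannot arise (patterns unique), but a full triangle can
  gt <- relate_seeds(build_seed_graph(c("ACA", "ACC", "CCA")), threshold = 4,
                     matrix = toy)
  expect_true(all(lengths(gt$related) == 2L))
})

test_that("motif construction aggregates aligned residues under both rules", {
  # a lone seed yields itself
  g <- relate_seeds(build_seed_graph(c("QPEQP", "WWWWW")), threshold = 5, matrix = pam)
  w <- setNames(c(10, 10), c("QPEQP", "WWWWW"))
  lone <- build_motif("WWWWW", g, w)
  expect_equal(lone$notation, "WWWWW")

  # two related seeds with equal weights and uniform expectation merge into
  # a bracket column where both residues clear the 1.5x and p rules
  g2 <- relate_seeds(build_seed_graph(c("QPEQP", "QPEQS")), threshold = 5, matrix = pam)
  w2 <- setNames(c(10, 10), c("QPEQP", "QPEQS"))
  m2 <- build_motif("QPEQP", g2, w2)
  expect_equal(m2$notation, "QPEQ[PS]")
  expect_equal(m2$connected_pattern_count, 1L)

  # a residue whose frequency only matches its expectation is excluded
  g3 <- relate_seeds(build_seed_graph(c("QAQ", "QCQ")), threshold = 1, matrix = pam)
  w3 <- setNames(c(100, 100), c("QAQ", "QCQ"))
  skew <- as_profile(setNames(ifelse(AA20 == "Q", 0.5,
                              ifelse(AA20 %in% c("A", "C"), 0.25, 0)), AA20))
  m3 <- build_motif("QAQ", g3, w3, expected_profile = skew)
  # Q columns: frequency 1 < 1.5 * 0.5? no, 1 >= 0.75 passes; A and C sit at
  # 0.5 each against 1.5 * 0.25 = 0.375, also passing -> [AC]
  expect_equal(m3$notation, "Q[AC]Q")
  skew2 <- as_profile(setNames(ifelse(AA20 == "Q", 0.2,
                               ifelse(AA20 %in% c("A", "C"), 0.4, 0)), AA20))
  m4 <- build_motif("QAQ", g3, w3, expected_profile = skew2)
  # now A and C (0.5 each) fall below 1.5 * 0.4 = 0.6 and drop out
  expect_equal(m4$notation, "QxQ")
})

test_that("motif pair scores take the best column story in the best frame", {
  m_id <- as_motif("QPE")
  expect_equal(motif_pair_score(m_id, m_id, pam),
               pam["Q", "Q"] + pam["P", "P"] + pam["E", "E"])
  s <- motif_pair_score(parse_motif("QPEQPF[PS]E"), parse_motif("QPEQPFSE"), pam)
  expect_gte(s, sum(diag(pam[c("Q", "P", "E", "Q", "P", "F", "S", "E"),
                             c("Q", "P", "E", "Q", "P", "F", "S", "E")])))
  # restricted to singleton top residues, motif scoring reduces to pattern
  # alignment
  pats <- withr::with_seed(52, sample(enumerate_patterns(3, 4, 6, c("A", "C", "P")), 10))
  for (i in 1:9) {
    expect_equal(motif_pair_score(as_motif(pats[i]), as_motif(pats[i + 1]), pam),
                 align_pattern_pair(pats[i], pats[i + 1], pam)$score)
  }
})

test_that("bulk motif scoring matches the scalar implementation", {
  motifs <- list(parse_motif("QPEQPF[PS]E"), parse_motif("QPEQPFSE"),
                 parse_motif("A[AC]A"), parse_motif("WxW[KW]"))
  masks <- lapply(motifs, imune:::scoring_masks)
  tops <- lapply(motifs, imune:::top_residue_codes)
  S <- imune:::cpp_motif_pair_scores(masks, tops, pam)
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      expect_equal(S[i, j], motif_pair_score(motifs[[i]], motifs[[j]], pam))
    }
  }
})

test_that("ranking and the non-redundant list respect seed usage", {
  cand <- function(notation, seed, conn, children, contributing) {
    structure(list(motif = parse_motif(notation), notation = notation,
                   source_seed = seed, connected_pattern_count = conn,
                   child_count = children, contributing_seeds = contributing,
                   pattern_weights = setNames(1, seed)),
              class = "motif_candidate")
  }
  expect_length(merge_and_rank(list()), 0L)
  one <- merge_and_rank(list(cand("QPE", "QPE", 3L, 1L, "QPE")))
  expect_equal(one[[1]]$notation, "QPE")
  expect_equal(one[[1]]$total_contributions, 3)

  cands <- list(cand("QPEQ", "QPEQ", 5L, 2L, c("QPEQ", "QPE")),
                cand("QPEQP", "QPE", 4L, 2L, c("QPE", "QPEQ")),
                cand("WKWKW", "WKW", 3L, 1L, "WKW"))
  ranked <- merge_and_rank(cands, threshold = 10, matrix = pam)
  # the two gliadin-like motifs are mutually related; the W motif is not
  expect_setequal(ranked[[1]]$related_motifs,
                  setdiff(c("QPEQ", "QPEQP"), ranked[[1]]$notation))
  expect_length(ranked[[3]]$related_motifs, 0L)
  expect_equal(ranked[[1]]$total_contributions, 9)
  expect_equal(ranked[[3]]$total_contributions, 3)

  nr <- nonredundant_list(ranked)
  # motif 2's source seed was used in making motif 1 -> dropped
  expect_length(nr, 2L)
  expect_equal(vapply(nr, `[[`, "", "source_seed"),
               c(ranked[[1]]$source_seed, "WKW"))

  # brute-force check of the greedy seed-usage rule on the same input
  used <- character(0)
  keep <- logical(length(ranked))
  for (i in seq_along(ranked)) {
    if (!(ranked[[i]]$source_seed %in% used)) {
      keep[i] <- TRUE
      used <- union(used, ranked[[i]]$contributing_seeds)
    }
  }
  expect_equal(vapply(nr, `[[`, "", "notation"),
               vapply(ranked[keep], `[[`, "", "notation"))
})

test_that("motif columns never invent residues absent from their patterns", {
  alpha <- study_alphabet()
  spec <- cohort_spec(4, 4, 4000, background_profile = subset_profile(alpha),
                      plants = list(list(motif = "QPEQPF[PS]E",
                                         case_fraction = 0.01,
                                         control_fraction = 0)),
                      seed = 91)
  coh <- simulate_cohort(spec)
  cfg <- run_config("i", cases = sprintf("case%02d", 1:4),
                    controls = sprintf("control%02d", 1:4), restriction = alpha)
  scan <- scan_cohort(coh$samples, cfg)
  motifs <- cluster_patterns(scan)
  used_residues <- unique(unlist(strsplit(gsub("x", "", scan$retained), "")))
  for (m in motifs) {
    res <- unlist(lapply(m$motif$columns, names))
    expect_true(all(res %in% used_residues))
  }
})
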