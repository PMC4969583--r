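test_that("plain-text reading aggregates duplicates and parses counts", {
  f <- withr::local_tempfile()
  writeLines(c("AAAAAAAAAAAA", "AAAAAAAAAAAA", "CCCCCCCCCCCC\t5"), f)
  rr <- read_sample_peptides(f, "plain")
  expect_s3_class(rr, "raw_reads")
  expect_equal(sort(rr$peptides), c("AAAAAAAAAAAA", "CCCCCCCCCCCC"))
  expect_equal(rr$counts[rr$peptides == "AAAAAAAAAAAA"], 2)
  expect_equal(rr$counts[rr$peptides == "CCCCCCCCCCCC"], 5)
  expect_equal(sum(rr$rejected), 0)
})

test_that("FASTA reading yields one record per entry with duplicate pooling", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACDEFGHIKLMN", ">r2", "PQRSTVWYACDE",
               ">r3", "AAAAAAAAAAAA", ">r4", "AAAAAAAAAAAA"), f)
  rr <- read_sample_peptides(f, "fasta")
  expect_equal(length(rr$peptides), 3L)
  expect_equal(rr$counts[rr$peptides == "AAAAAAAAAAAA"], 2)
  expect_equal(rr$counts[rr$peptides == "ACDEFGHIKLMN"], 1)
})

test_that("length and alphabet failures are excluded and tallied", {
  f <- withr::local_tempfile()
  writeLines(c("AAAAAAAAAAAA", "AAAAAAAAAAA", "AAAAAAAAAAAB"), f)  # 11-mer, B
  rr <- read_sample_peptides(f, "plain")
  expect_equal(length(rr$peptides), 1L)
  expect_equal(unname(rr$rejected["length"]), 1L)
  expect_equal(unname(rr$rejected["alphabet"]), 1L)
  f2 <- withr::local_tempfile()
  writeLines("AAAA", f2)
  expect_error(read_sample_peptides(f2, "plain"), "no valid peptide")
})

test_that("collapse absorbs near-duplicates up to the mutation threshold", {
  p1 <- "AAAAAAAAAAAA"
  p_d3 <- "CCCAAAAAAAAA"  # Hamming 3 from p1
  p_d4 <- "CCCCAAAAAAAA"  # Hamming 4 from p1
  ps <- build_nonredundant_set(make_reads(c(p1, p_d3), c(10, 1)))
  expect_equal(ps$peptides, p1)
  expect_equal(ps$N, 1L)
  ps2 <- build_nonredundant_set(make_reads(c(p1, p_d4), c(10, 1)))
  expect_equal(sort(ps2$peptides), sort(c(p1, p_d4)))
  # repeated observations of one peptide normalize to one
  ps3 <- build_nonredundant_set(make_reads(c(p1, p1), c(7, 2)))
  expect_equal(ps3$N, 1L)
})

test_that("collapse is idempotent, order-invariant and never grows the set", {
  peps <- random_peptides(60, alphabet = c("A", "C", "D"), seed = 11)
  counts <- rev(seq_along(peps))
  ps <- build_nonredundant_set(make_reads(peps, counts), max_mutations = 3)
  expect_lte(ps$N, length(peps))
  # idempotence: collapsing the retained set (all counts 1) changes nothing
  ps_again <- build_nonredundant_set(make_reads(ps$peptides), max_mutations = 3)
  expect_equal(ps_again$peptides, ps$peptides)
  # order invariance
  perm <- withr::with_seed(5, sample(seq_along(peps)))
  ps_perm <- build_nonredundant_set(make_reads(peps[perm], counts[perm]),
                                    max_mutations = 3)
  expect_identical(ps_perm$peptides, ps$peptides)
  # max_mutations = 0 keeps every distinct peptide
  ps0 <- build_nonredundant_set(make_reads(peps, counts), max_mutations = 0)
  expect_equal(ps0$N, length(peps))
  expect_error(build_nonredundant_set(make_reads(peps), max_mutations = -1))
  expect_error(build_nonredundant_set(make_reads(peps), max_mutations = 12))
})

test_that("frequency profiles count residues across all positions", {
  expect_equal(unname(amino_acid_frequencies("AAAAAAAAAAAA")["A"]), 1)
  f <- amino_acid_frequencies("AAAAAAAAAAAC")
  expect_equal(unname(f["A"]), 11 / 12)
  expect_equal(unname(f["C"]), 1 / 12)
  expect_equal(sum(f), 1)
  expect_error(amino_acid_frequencies(character(0)))
})

test_that("profiles of large uniform samples match the binomial oracle", {
  ps <- background_sample(10000, seed = 99, sample_id = "u")
  se <- sqrt(0.05 * 0.95 / (10000 * 12))
  expect_true(all(abs(ps$profile - 0.05) < 3.5 * se))
  expect_equal(sum(ps$profile), 1)
})

test_that("peptide sets round-trip through disk with their JSON sidecar", {
  ps <- background_sample(50, seed = 7, sample_id = "s1")
  f <- withr::local_tempfile()
  write_peptide_set(ps, f)
  back <- build_nonredundant_set(read_sample_peptides(f, "plain", sample_id = "s1"),
                                 max_mutations = 0)
  expect_identical(back$peptides, ps$peptides)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$N, ps$N)
  expect_equal(side$sample_id, "s1")
})
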