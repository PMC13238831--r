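test_that("local alignment reports identity and matches the DP score oracle", {
  set.seed(1)
  s <- rand_nt(100)
  same <- align_local(s, s)
  expect_equal(same$identity, 100)

  # internal mismatch within a full-length local alignment
  r <- align_local("ACGTACGT", "ACGAACGT")
  expect_equal(r$identity, 100 * 7 / 8)

  nmat <- nt_score_matrix()
  for (k in 1:10) {
    a <- rand_nt(60); b <- rand_nt(60)
    expect_equal(align_local(a, b)$score, sw_score_oracle(a, b, nmat))
  }
  bmat <- blosum62_matrix()
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (k in 1:5) {
    a <- paste(sample(aa, 40, TRUE), collapse = "")
    b <- paste(sample(aa, 40, TRUE), collapse = "")
    expect_equal(align_local(a, b, type = "protein")$score,
                 sw_score_oracle(a, b, bmat))
  }
})

test_that("closest_reference finds exact and synonymous matches", {
  set.seed(2)
  lib <- sim_allele_library("UBA", K = 5, lineage_count = 2, seed = 3)
  hit <- closest_reference(lib$sequence[3], lib)
  expect_equal(hit$reference, lib$name[3])
  expect_equal(hit$nt_identity, 100)
  expect_equal(hit$aa_identity, 100)
  expect_true(hit$nt_identical)

  syn <- syn_mutate(lib$sequence[3], 10)
  expect_false(identical(syn, lib$sequence[3]))
  hit2 <- closest_reference(syn, lib)
  expect_equal(hit2$reference, lib$name[3])
  expect_lt(hit2$nt_identity, 100)
  expect_equal(hit2$aa_identity, 100)
  expect_equal(hit2$aa_diff, 0L)
})

test_that("the naming decision table follows the amino-acid distance rules", {
  set.seed(4)
  base <- rand_coding(87)
  lib <- tibble::tibble(
    name = c("DAA*01:01", "DAA*03:03:01"),
    locus = "DAA", field1 = c(1L, 3L), field2 = c(1L, 3L),
    field3 = c(NA_integer_, 1L), suffix = NA_character_,
    sequence = c(base, mutate_codons(base, c(10, 20, 30, 40, 50))),
    peptide = NA_character_, lineage = NA_character_, novel = FALSE
  )
  lib$peptide <- vapply(lib$sequence, function(s)
    tr_nt(s), character(1),
    USE.NAMES = FALSE)

  # 2 aa from DAA*01:01 -> new four-digit in family 01
  q <- mutate_codons(base, c(5, 6))
  res <- assign_allele_name(q, "DAA", lib)
  expect_equal(res$record$name, "DAA*01:02")
  expect_equal(res$report$decision, "new_protein_variant")
  expect_true(res$record$novel)

  # synonymous variant of DAA*03:03:01 -> DAA*03:03:02
  qs <- syn_mutate(lib$sequence[2], 15)
  res2 <- assign_allele_name(qs, "DAA", lib)
  expect_equal(res2$record$name, "DAA*03:03:02")
  expect_equal(res2$report$decision, "synonymous_extension")

  # 4 aa for DAA (> 3) -> new two-digit family
  q4 <- mutate_codons(base, c(3, 9, 27, 60))
  res3 <- assign_allele_name(q4, "DAA", lib)
  expect_equal(res3$record$name, "DAA*04:01")
  expect_equal(res3$report$decision, "new_family")

  # longer sequence identical over the matched span -> _L suffix
  ql <- paste0(base, "GGTTCA")
  res4 <- assign_allele_name(ql, "DAA", lib)
  expect_equal(res4$record$name, "DAA*01:01_L")
  expect_equal(res4$report$decision, "long_variant")
})

test_that("UBA tolerates up to 4 aa within a family (rule is 'more than 4')", {
  set.seed(5)
  base <- rand_coding(86)
  lib <- tibble::tibble(
    name = "UBA*01:01", locus = "UBA", field1 = 1L, field2 = 1L,
    field3 = NA_integer_, suffix = NA_character_, sequence = base,
    peptide = tr_nt(base),
    lineage = NA_character_, novel = FALSE
  )
  q4 <- mutate_codons(base, c(5, 15, 25, 35))
  expect_equal(assign_allele_name(q4, "UBA", lib)$record$name, "UBA*01:02")
  q5 <- mutate_codons(base, c(5, 15, 25, 35, 45))
  expect_equal(assign_allele_name(q5, "UBA", lib)$record$name, "UBA*02:01")
})

test_that("naming is idempotent and reruns give identical classifications", {
  lib <- sim_allele_library("DAB", K = 3, seed = 6)
  set.seed(7)
  novel <- mutate_codons(lib$sequence[1], c(4, 8))
  cand <- tibble::tibble(sequence = c(novel, lib$sequence[2]), locus = "DAB",
                         support = c(120, 300))
  first <- classify_alleles(cand, lib)
  again <- classify_alleles(cand, first$library)
  expect_equal(first$map$name, again$map$name)
  expect_false(any(again$map$novel))
  expect_equal(nrow(again$library), nrow(first$library))
})

test_that("two-digit families equal single-linkage clusters on a structured library", {
  set.seed(8)
  base <- rand_coding(87)
  protos <- list(base,
                 mutate_codons(base, seq(2, 80, by = 6)),
                 mutate_codons(base, seq(4, 82, by = 6)),
                 mutate_codons(base, seq(3, 81, by = 5)))
  seqs <- unlist(lapply(protos, function(p) {
    c(p, syn_mutate(mutate_codons(p, 11), 2), mutate_codons(p, c(17, 19)))
  }))
  peps <- vapply(seqs, function(s)
    tr_nt(s), character(1),
    USE.NAMES = FALSE)
  oracle_k <- single_linkage_families(peps, threshold = 3)

  lib0 <- tibble::tibble(
    name = "DAB*01:01", locus = "DAB", field1 = 1L, field2 = 1L,
    field3 = NA_integer_, suffix = NA_character_, sequence = seqs[1],
    peptide = peps[1], lineage = NA_character_, novel = FALSE
  )
  res <- classify_alleles(
    tibble::tibble(sequence = seqs[-1], locus = "DAB",
                   support = rev(seq_along(seqs[-1]))),
    lib0
  )
  got_k <- length(unique(res$library$field1))
  expect_equal(got_k, oracle_k)
})

test_that("Jukes-Cantor distance matches the closed form and saturates", {
  s <- strrep("ACGT", 30)
  expect_equal(jc_distance(s, s), 0)

  # p = 195/2048 differing sites
  a <- paste(rep("A", 2048), collapse = "")
  b <- paste(c(rep("C", 195), rep("A", 2048 - 195)), collapse = "")
  p <- 195 / 2048
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 4 * p / 3))

  # monotone increasing in p
  ds <- vapply(c(50, 150, 300, 450), function(k) {
    bb <- paste(c(rep("C", k), rep("A", 2048 - k)), collapse = "")
    jc_distance(a, bb)
  }, numeric(1))
  expect_true(all(diff(ds) > 0))

  # saturation and short-alignment guards
  sat <- paste(rep("C", 2048), collapse = "")
  expect_true(is.na(jc_distance(a, sat)))
  expect_error(jc_distance("ACGT", "ACGT"), "ungapped")
})

test_that("lineage assignment recovers the construction and respects the pool partition", {
  lib <- sim_allele_library("UBA", K = 8, lineage_count = 4, seed = 9)
  ex <- lineage_exemplars(lib)
  # an exemplar maps to its own lineage with positive margin
  self <- assign_lineage(ex$sequence[1], ex)
  expect_equal(self$lineage, ex$lineage[1])
  expect_gt(self$margin, 0)

  # full alleles (alpha-1 + foreign alpha-2) map back to their lineage
  for (i in seq_len(nrow(lib))) {
    got <- assign_lineage(lib$sequence[i], ex)
    expect_equal(got$lineage, lib$lineage[i])
  }

  # each lineage served by exactly one UBA pool, as in the primer design
  primers <- default_primers("UBA")
  pools <- vapply(lib$lineage, function(l) mhcdiv:::pool_for_allele("UBA", l, primers),
                  character(1))
  expect_true(all(pools %in% primers$pool))
  lin_by_pool <- split(lib$lineage, pools)
  served <- stats::setNames(primers$lineages, primers$pool)
  for (p in names(lin_by_pool)) {
    expect_true(all(lin_by_pool[[p]] %in% served[[p]]))
  }
})
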