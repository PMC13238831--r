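make_pair <- function(template, primers, pool, read_length = 300) {
  pr <- primers[primers$pool == pool, ]
  amp <- paste0(pr$forward, template,
                as.character(Biostrings::reverseComplement(Biostrings::DNAString(pr$reverse))))
  r1 <- substr(amp, 1, min(nchar(amp), read_length))
  r2 <- substr(rc(amp), 1, min(nchar(amp), read_length))
  tibble::tibble(individual = "i1", read1 = r1, read2 = r2,
                 qual1 = strrep("I", nchar(r1)), qual2 = strrep("I", nchar(r2)))
}

test_that("primer demultiplexing is exact-match only and strips primers", {
  primers <- default_primers()
  set.seed(1)
  template <- rand_nt(260)
  rp <- make_pair(template, primers, "UBA.F1")
  dmx <- demultiplex_reads(rp, primers)
  expect_equal(dmx$pool, "UBA.F1")
  expect_false(startsWith(dmx$read1, primers$forward[primers$pool == "UBA.F1"]))

  # one mismatch in the forward primer leaves the pair unassigned
  bad <- rp
  f <- primers$forward[primers$pool == "UBA.F1"]
  sub <- if (substr(f, 5, 5) == "A") "C" else "A"
  bad$read1 <- paste0(substr(f, 1, 4), sub, substr(f, 6, nchar(f)),
                      substr(rp$read1, nchar(f) + 1, nchar(rp$read1)))
  dmx2 <- demultiplex_reads(bad, primers)
  expect_true(is.na(dmx2$pool))
  expect_identical(dmx2$read1, bad$read1)  # unstripped

  # empty input
  empty <- demultiplex_reads(rp[0, ], primers)
  expect_equal(nrow(empty), 0)

  # two pools with the same forward primer is a malformed configuration
  dup <- primers
  dup$forward[2] <- dup$forward[1]
  expect_error(demultiplex_reads(rp, dup), "distinct forward")
})

test_that("pair merging picks the best admissible overlap in either orientation", {
  set.seed(2)
  frag <- rand_nt(150)
  r1 <- substr(frag, 1, 100)
  r2 <- rc(substr(frag, 51, 150))
  reads <- tibble::tibble(individual = "x", read1 = r1, read2 = r2,
                          qual1 = strrep("I", 100), qual2 = strrep("I", 100))
  m <- merge_read_pairs(reads)
  expect_equal(nchar(m$merged), 100 + 100 - 50)
  expect_equal(m$merged, frag)

  # no admissible overlap of >= 10 bases
  reads2 <- tibble::tibble(individual = "x", read1 = rand_nt(60),
                           read2 = rand_nt(60),
                           qual1 = strrep("I", 60), qual2 = strrep("I", 60))
  expect_true(is.na(merge_read_pairs(reads2)$merged))

  # disagreeing overlap base follows the higher quality read
  r1b <- r1
  substr(r1b, 80, 80) <- if (substr(r1, 80, 80) == "A") "G" else "A"
  q_low <- strrep("I", 100); substr(q_low, 80, 80) <- "$"
  hi <- merge_read_pairs(tibble::tibble(individual = "x", read1 = r1b, read2 = r2,
                                        qual1 = strrep("I", 100),
                                        qual2 = strrep("$", 100)))
  expect_equal(substr(hi$merged, 80, 80), substr(r1b, 80, 80))
  lo <- merge_read_pairs(tibble::tibble(individual = "x", read1 = r1b, read2 = r2,
                                        qual1 = q_low, qual2 = strrep("I", 100)))
  expect_equal(substr(lo$merged, 80, 80), substr(frag, 80, 80))
})

test_that("merging agrees with the exhaustive overlap-enumeration oracle", {
  set.seed(3)
  for (k in 1:25) {
    L <- sample(60:120, 1)
    frag <- rand_nt(L)
    l1 <- sample(40:L, 1); l2 <- sample(40:L, 1)
    r1 <- substr(frag, 1, l1)
    r2 <- rc(substr(frag, L - l2 + 1, L))
    # sprinkle errors
    mut <- function(s, k) {
      for (i in sample(nchar(s), k)) {
        substr(s, i, i) <- sample(setdiff(NT, substr(s, i, i)), 1)
      }
      s
    }
    r1 <- mut(r1, sample(0:2, 1)); r2 <- mut(r2, sample(0:2, 1))
    q1 <- paste(sample(strsplit("#5AI", "")[[1]], nchar(r1), TRUE), collapse = "")
    q2 <- paste(sample(strsplit("#5AI", "")[[1]], nchar(r2), TRUE), collapse = "")
    got <- merge_read_pairs(tibble::tibble(individual = "x", read1 = r1,
                                           read2 = r2, qual1 = q1, qual2 = q2))$merged
    expect_identical(got, merge_oracle(r1, r2, q1, q2))
  }
})

test_that("collapse ranks unique reads deterministically and matches dictionary counting", {
  cs <- collapse_reads(c("A", "A", "B"))
  expect_equal(cs$sequence, c("A", "B"))
  expect_equal(cs$count, c(2L, 1L))

  empty <- collapse_reads(character(0))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total"), 0L)

  set.seed(4)
  seqs <- replicate(10000, rand_nt(4))
  cs <- collapse_reads(seqs)
  oracle <- sort(table(seqs), decreasing = TRUE)
  expect_equal(sum(cs$count), 10000L)
  expect_equal(stats::setNames(cs$count, cs$sequence)[names(oracle)],
               stats::setNames(as.integer(oracle), names(oracle)))
  # ties broken lexicographically
  expect_true(all(diff(order(-cs$count, cs$sequence)) > 0))
})

test_that("candidate selection applies the count-fraction floor and the top-five cap", {
  cs <- tibble::tibble(sequence = letters[1:6],
                       count = c(500L, 480L, 6L, 3L, 2L, 1L))
  kept <- select_candidates(cs, total = 1000)
  expect_equal(nrow(kept), 2)

  cs2 <- tibble::tibble(sequence = letters[1:6], count = rep(100L, 6))
  expect_equal(nrow(select_candidates(cs2, total = 600)), 5)

  cs3 <- tibble::tibble(sequence = letters[1:3], count = c(3L, 2L, 1L))
  expect_equal(nrow(select_candidates(cs3, total = 1000)), 0)
})

test_that("frame adjustment finds the stop-free trim and equals brute force on random sequences", {
  set.seed(5)
  cds <- rand_coding(60)
  fa <- adjust_reading_frame(cds)
  expect_equal(c(fa$offset5, fa$offset3), c(0L, 0L))
  expect_equal(fa$trimmed, cds)

  shifted <- adjust_reading_frame(paste0("G", cds))
  expect_equal(c(shifted$offset5, shifted$offset3), c(1L, 0L))
  expect_identical(shifted$peptide, fa$peptide)

  # brute-force oracle over the 9 trims
  oracle <- function(s) {
    best <- NULL
    for (o5 in 0:2) for (o3 in 0:2) {
      sub <- substr(s, 1 + o5, nchar(s) - o3)
      sub3 <- substr(sub, 1, nchar(sub) %/% 3 * 3)
      pep <- tr_nt(sub3)
      core <- sub("\\*$", "", pep)
      if (grepl("*", core, fixed = TRUE)) next
      if (is.null(best) || nchar(core) > best$len) {
        best <- list(o5 = o5, o3 = o3, len = nchar(core), pep = core)
      }
    }
    best
  }
  for (k in 1:30) {
    s <- rand_nt(300)
    got <- adjust_reading_frame(s)
    want <- oracle(s)
    if (is.null(want)) {
      expect_false(got$valid)
    } else {
      expect_equal(c(got$offset5, got$offset3), c(want$o5, want$o3))
      expect_equal(got$peptide, want$pep)
    }
  }
})

test_that("genotype calling keeps at most two alleles and flags anomalies", {
  two_pools <- tibble::tibble(individual = "i1", locus = "UBA",
                              name = c("UBA*13:01", "UBA*24:01"),
                              support = c(400, 380))
  call <- call_genotypes(two_pools)
  expect_equal(c(call$allele1, call$allele2), c("UBA*13:01", "UBA*24:01"))
  expect_true(is.na(call$flags))

  hom <- call_genotypes(tibble::tibble(individual = "i1", locus = "UBA",
                                       name = "UBA*13:01", support = 400))
  expect_equal(c(hom$allele1, hom$allele2), c("UBA*13:01", "UBA*13:01"))
  expect_true(is.na(hom$flags))

  low <- call_genotypes(tibble::tibble(individual = "i1", locus = "UBA",
                                       name = "UBA*13:01", support = 30))
  expect_match(low$flags, "low_support")

  three <- call_genotypes(tibble::tibble(individual = "i1", locus = "UBA",
                                         name = c("a", "b", "c"),
                                         support = c(400, 390, 12)))
  expect_setequal(c(three$allele1, three$allele2), c("a", "b"))
  expect_match(three$flags, "excess_alleles")
})

test_that("the pipeline conserves reads and is invariant to input read order", {
  lib <- dplyr::bind_rows(sim_allele_library("UBA", K = 5, lineage_count = 3, seed = 8),
                          sim_allele_library("DAB", K = 4, seed = 9))
  gt <- dplyr::bind_rows(
    sim_genotypes(sim_allele_freqs(5, "geometric", r = 0.8), 3,
                  alleles = lib$name[lib$locus == "UBA"], locus = "UBA", seed = 3),
    sim_genotypes(sim_allele_freqs(4, "geometric", r = 0.8), 3,
                  alleles = lib$name[lib$locus == "DAB"], locus = "DAB", seed = 4)
  )
  sr <- sim_reads(gt, lib, depth = 150, error_rate = 0.01, seed = 21)
  res <- genotype_amplicons(sr$reads, default_primers(), lib)
  st <- res$stats
  expect_equal(st$low_quality + st$assigned + st$unassigned, st$input_pairs)
  expect_equal(st$merged + st$unmerged, st$assigned)

  set.seed(10)
  shuffled <- sr$reads[sample(nrow(sr$reads)), ]
  res2 <- genotype_amplicons(shuffled, default_primers(), lib)
  expect_equal(dplyr::arrange(res$genotypes, individual, locus),
               dplyr::arrange(res2$genotypes, individual, locus))
})

test_that("missing genotypes are reported when no candidate survives", {
  lib <- sim_allele_library("DAB", K = 2, seed = 12)
  reads <- tibble::tibble(individual = "i1",
                          read1 = rand_nt(100), read2 = rand_nt(100),
                          qual1 = strrep("I", 100), qual2 = strrep("I", 100))
  res <- genotype_amplicons(reads, default_primers("DAB"), lib)
  expect_true(all(is.na(res$genotypes$allele1)))
  expect_match(res$genotypes$flags, "missing")
})
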