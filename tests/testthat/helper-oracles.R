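# Independent oracles and fixture builders used across test files.

NT <- c("A", "C", "G", "T")

rand_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

# Gotoh local-alignment score with affine gaps costed as open + ext * length
# (independent of Biostrings; used to check align_local scores).
sw_score_oracle <- function(a, b, smat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      s <- smat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      best <- max(best, M[i, j])
    }
  }
  best
}

nt_score_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                           baseOnly = TRUE)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Enumerate every admissible overlap in both orientations and merge; mirrors
# the documented merge semantics in plain R.
merge_oracle <- function(r1, r2, q1, q2, min_overlap = 10, max_mm = 0.25) {
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(rc(r2), "")[[1]]
  qa <- utf8ToInt(q1)
  qb <- rev(utf8ToInt(q2))
  L1 <- length(a)
  L2 <- length(b)
  best <- NULL
  better <- function(m, innie, o) {
    if (is.null(best)) return(TRUE)
    if (m != best$m) return(m > best$m)
    if (innie != best$innie) return(innie)
    o > best$o
  }
  for (o in min_overlap:min(L1, L2)) {
    m <- sum(a[(L1 - o + 1):L1] == b[1:o])
    if ((o - m) <= max_mm * o && better(m, TRUE, o)) {
      best <- list(m = m, o = o, innie = TRUE)
    }
    m2 <- sum(a[1:o] == b[(L2 - o + 1):L2])
    if ((o - m2) <= max_mm * o && better(m2, FALSE, o)) {
      best <- list(m = m2, o = o, innie = FALSE)
    }
  }
  if (is.null(best)) return(NA_character_)
  o <- best$o
  if (best$innie) {
    cons <- character(o)
    for (j in 1:o) {
      ia <- L1 - o + j
      cons[j] <- if (a[ia] == b[j]) a[ia] else if (qb[j] > qa[ia]) b[j] else a[ia]
    }
    paste(c(a[seq_len(L1 - o)], cons, b[(o + 1):L2][seq_len(L2 - o)]),
          collapse = "")
  } else {
    cons <- character(o)
    for (j in 1:o) {
      ib <- L2 - o + j
      cons[j] <- if (a[j] == b[ib]) a[j] else if (qb[ib] > qa[j]) b[ib] else a[j]
    }
    paste(cons, collapse = "")
  }
}

# Frame-0 translation without initiator-codon special-casing (these are
# mid-gene amplicon fragments, not CDS starts) - matches the package.
tr_nt <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

# Stop-free random coding sequence of n_codons codons.
rand_coding <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste(sample(NT, 3, replace = TRUE), collapse = "")
      if (!cod %in% stops) break
    }
    cods[i] <- cod
  }
  paste(cods, collapse = "")
}

# Replace the codons at `positions` with a codon for a different amino acid
# (non-synonymous edit that cannot create a stop).
mutate_codons <- function(seq, positions) {
  for (k in positions) {
    i <- 3 * (k - 1) + 1
    old <- substr(seq, i, i + 2)
    new <- if (tr_nt(old) == "A") "GTT" else "GCT"  # Val unless already Ala
    substr(seq, i, i + 2) <- new
  }
  seq
}

# Synonymous third-base edit at or after codon k (scans forward past
# Met/Trp codons, which have no synonymous variant).
syn_mutate <- function(seq, k) {
  n <- nchar(seq) %/% 3
  for (kk in c(k:n, seq_len(k - 1))) {
    i <- 3 * (kk - 1) + 1
    old <- substr(seq, i, i + 2)
    for (b in NT) {
      cand <- paste0(substr(old, 1, 2), b)
      if (cand != old && !cand %in% c("TAA", "TAG", "TGA") &&
          tr_nt(cand) == tr_nt(old)) {
        substr(seq, i, i + 2) <- cand
        return(seq)
      }
    }
  }
  stop("no synonymous site available")
}

# Single-linkage cluster count with edges where aa distance <= threshold.
single_linkage_families <- function(peptides, threshold) {
  n <- length(peptides)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      aln <- align_local(peptides[i], peptides[j], type = "protein")
      d <- aln$columns - aln$matches
      adj[i, j] <- adj[j, i] <- d <= threshold
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          mn <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- mn
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Draw a two-locus population from known haplotype frequencies; returns the
# long genotype table and the true per-individual haplotype pairs.
sim_haplotype_population <- function(haps, freqs, n, seed) {
  set.seed(seed)
  idx1 <- sample.int(nrow(haps), n, replace = TRUE, prob = freqs)
  idx2 <- sample.int(nrow(haps), n, replace = TRUE, prob = freqs)
  ind <- sprintf("hap_%04d", seq_len(n))
  gt <- dplyr::bind_rows(
    tibble::tibble(individual = ind, population = "p", group = "wild",
                   sex = "F", locus = "DAA",
                   allele1 = pmin(haps$daa[idx1], haps$daa[idx2]),
                   allele2 = pmax(haps$daa[idx1], haps$daa[idx2])),
    tibble::tibble(individual = ind, population = "p", group = "wild",
                   sex = "F", locus = "DAB",
                   allele1 = pmin(haps$dab[idx1], haps$dab[idx2]),
                   allele2 = pmax(haps$dab[idx1], haps$dab[idx2]))
  )
  truth <- tibble::tibble(
    individual = ind,
    hap1 = pmin(paste(haps$daa[idx1], haps$dab[idx1], sep = "~"),
                paste(haps$daa[idx2], haps$dab[idx2], sep = "~")),
    hap2 = pmax(paste(haps$daa[idx1], haps$dab[idx1], sep = "~"),
                paste(haps$daa[idx2], haps$dab[idx2], sep = "~"))
  )
  list(genotypes = gt, truth = truth)
}

# Full simulate-reads -> genotype pipeline run; returns per-genotype
# correctness against the truth manifest.
recovery_run <- function(seed, n_ind = 5, depth = 500, error_rate = 0.01) {
  lib <- dplyr::bind_rows(
    sim_allele_library("UBA", K = 6, lineage_count = 3, seed = seed),
    sim_allele_library("DAA", K = 4, seed = seed + 1000),
    sim_allele_library("DAB", K = 4, seed = seed + 2000)
  )
  gt <- dplyr::bind_rows(lapply(c("UBA", "DAA", "DAB"), function(lc) {
    K <- sum(lib$locus == lc)
    sim_genotypes(sim_allele_freqs(K, "geometric", r = 0.8), n_ind,
                  alleles = lib$name[lib$locus == lc], locus = lc,
                  population = paste0("s", seed), seed = seed + 17)
  }))
  sr <- sim_reads(gt, lib, default_primers(), depth = depth,
                  error_rate = error_rate, seed = seed)
  res <- genotype_amplicons(sr$reads, default_primers(), lib)
  truth <- dplyr::mutate(sr$truth,
                         t1 = pmin(allele1, allele2),
                         t2 = pmax(allele1, allele2))
  cmp <- dplyr::inner_join(res$genotypes,
                           truth[, c("individual", "locus", "t1", "t2")],
                           by = c("individual", "locus"))
  cmp$correct <- !is.na(cmp$allele1) & cmp$allele1 == cmp$t1 & cmp$allele2 == cmp$t2
  cmp
}
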