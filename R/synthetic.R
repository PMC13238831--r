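# Synthetic allele libraries, frequency spectra, genotypes and paired reads
# with known truth, emulating the structure of salmon MHC amplicon studies.

UBA_ALPHA1_NT <- 236L  # alpha-1 domain length used throughout (nt)
UBA_ALPHA2_NT <- 24L   # divergent alpha-2 background; keeps the amplicon
                       # within one 300 nt read so pairs double-cover it
CLASSII_NT <- 261L     # class II fragment length (nt)

ROMAN <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

random_nt <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutate_nt <- function(s, rate) {
  v <- chars(s)
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

# Replace any stop codon (frame 0) by changing its third base to C
# (TAA->TAC Tyr, TAG->TAC, TGA->TGC Cys), keeping sequences stop-free.
fix_stops <- function(s) {
  v <- chars(s)
  n <- length(v) %/% 3L
  for (k in seq_len(n)) {
    i <- 3L * (k - 1L)
    if (paste(v[i + 1:3], collapse = "") %in% STOP_CODONS) v[i + 3L] <- "C"
  }
  paste(v, collapse = "")
}

#' Simulate an MHC allele reference library
#'
#' For the class I locus (`UBA`) every allele is a concatenation of an
#' alpha-1 domain drawn from one of `lineage_count` ancient lineages and an
#' allele-specific alpha-2 background, echoing the intron-mediated domain
#' shuffling that generates class I diversity: when `K >= 2` the first two
#' alleles share an identical alpha-1 but differ in alpha-2 (the shuffling
#' signature). Class II (`DAA`/`DAB`) alleles are single fragments differing
#' pairwise by at least one nucleotide. All sequences are stop-free in
#' frame 0.
#'
#' @param locus `"UBA"`, `"DAA"` or `"DAB"`.
#' @param K Number of alleles (true allele count).
#' @param lineage_count Number of alpha-1 lineages (UBA only, at most 8).
#' @param within_rate,between_rate Per-site substitution rates within a
#'   lineage and between lineage prototypes.
#' @param alpha2_rate Per-site substitution rate among alpha-2 backgrounds
#'   (UBA) or among class II alleles.
#' @param seed Integer seed.
#' @return Allele library tibble as in [read_allele_fasta()], with `lineage`
#'   set for UBA and extra `alpha1`/`alpha2` columns recording the
#'   construction.
#' @export
sim_allele_library <- function(locus, K, lineage_count = 3, within_rate = 0.02,
                               between_rate = 0.25, alpha2_rate = 0.15,
                               seed = 1) {
  locus <- match.arg(locus, c("UBA", "DAA", "DAB"))
  stopifnot(K >= 1)
  if (locus == "UBA" && (lineage_count < 1 || lineage_count > 8)) {
    stop("UBA lineage_count must be in 1..8")
  }
  set.seed(derive_seed(seed, paste0("lib", locus)))

  if (locus == "UBA") {
    base1 <- random_nt(UBA_ALPHA1_NT)
    protos <- vapply(seq_len(lineage_count),
                     function(i) mutate_nt(base1, between_rate), character(1))
    lin_idx <- if (K == 1) 1L else c(1L, 1L, rep_len(seq_len(lineage_count), K - 2L))
    alpha1 <- vapply(seq_len(K), function(i) {
      if (i <= 2L) protos[1L] else mutate_nt(protos[lin_idx[i]], within_rate)
    }, character(1))
    base2 <- random_nt(UBA_ALPHA2_NT)
    alpha2 <- vapply(seq_len(K), function(i) mutate_nt(base2, alpha2_rate),
                     character(1))
    seqs <- vapply(paste0(alpha1, alpha2), fix_stops, character(1),
                   USE.NAMES = FALSE)
    lineage <- ROMAN[lin_idx]
  } else {
    base <- random_nt(CLASSII_NT)
    seqs <- vapply(seq_len(K), function(i) fix_stops(mutate_nt(base, alpha2_rate)),
                   character(1))
    alpha1 <- rep(NA_character_, K)
    alpha2 <- rep(NA_character_, K)
    lineage <- rep(NA_character_, K)
  }

  # enforce pairwise-distinct nucleotide sequences (>= 1 nt apart)
  for (tries in 1:200) {
    dup <- which(duplicated(seqs))
    if (length(dup) == 0) break
    for (i in dup) {
      v <- chars(seqs[i])
      pos <- if (locus == "UBA") UBA_ALPHA1_NT + sample.int(UBA_ALPHA2_NT, 1)
             else sample.int(CLASSII_NT, 1)
      v[pos] <- sample(setdiff(BASES, v[pos]), 1)
      s <- fix_stops(paste(v, collapse = ""))
      if (locus == "UBA") {
        alpha2[i] <- substr(s, UBA_ALPHA1_NT + 1L, nchar(s))
      }
      seqs[i] <- s
    }
  }
  if (anyDuplicated(seqs)) {
    stop("could not build ", K, " distinct alleles at this length: ",
         "divergence constraints impossible")
  }
  if (K >= 2 && locus == "UBA") {
    alpha1[2] <- alpha1[1]  # construction guarantee, recorded explicitly
  }

  tibble::tibble(
    name = format_allele_name(locus, seq_len(K), 1L),
    locus = locus,
    field1 = seq_len(K),
    field2 = 1L,
    field3 = NA_integer_,
    suffix = NA_character_,
    sequence = seqs,
    peptide = translate_nt(seqs),
    lineage = lineage,
    novel = FALSE,
    alpha1 = alpha1,
    alpha2 = alpha2
  )
}

#' Simulate a population allele-frequency spectrum
#'
#' @param K Number of alleles.
#' @param model `"geometric"` gives \eqn{p_i \propto r^{i-1}} (skewed spectra
#'   with many rare alleles for small `r`); `"dirichlet"` draws a random
#'   composition with concentration `alpha`.
#' @param r Geometric ratio in (0, 1]; `r = 1` is uniform.
#' @param alpha Dirichlet concentration (> 0).
#' @param seed Integer seed (used by the Dirichlet model).
#' @return Numeric vector of `K` frequencies summing to 1.
#' @export
sim_allele_freqs <- function(K, model = c("geometric", "dirichlet"), r = 0.8,
                             alpha = 1, seed = 1) {
  model <- match.arg(model)
  stopifnot(K >= 1)
  if (model == "geometric") {
    if (r <= 0 || r > 1) stop("geometric ratio r must be in (0, 1]")
    w <- r^(seq_len(K) - 1)
  } else {
    stopifnot(alpha > 0)
    set.seed(derive_seed(seed, "freqs"))
    w <- stats::rgamma(K, shape = alpha)
    while (sum(w) == 0) w <- stats::rgamma(K, shape = alpha)
  }
  w / sum(w)
}

#' Simulate diploid genotypes with optional homozygote excess
#'
#' Each individual receives an unordered allele pair. With inbreeding-style
#' coefficient `f`, the genotype distribution is
#' \eqn{P(ii) = p_i^2 + f p_i (1 - p_i)} and
#' \eqn{P(ij) = 2 p_i p_j (1 - f)}, so `f = 0` is Hardy-Weinberg equilibrium
#' and `f = 1` makes every individual homozygous. Marginal allele
#' frequencies are unbiased for `p` at any `f`.
#'
#' @param freqs Frequency vector (sums to 1). Names, if present, are used as
#'   allele labels; otherwise `alleles` or generated labels are used.
#' @param n Number of individuals.
#' @param f Homozygote-excess coefficient in \[0, 1\].
#' @param alleles Optional allele labels (e.g. `library$name`).
#' @param locus,population,group Labels stamped on every row.
#' @param seed Integer seed.
#' @return Long genotype tibble (`individual`, `population`, `group`, `sex`,
#'   `locus`, `allele1`, `allele2`), pairs sorted within row.
#' @export
sim_genotypes <- function(freqs, n, f = 0, alleles = NULL, locus = "UBA",
                          population = "pop1", group = "wild", seed = 1) {
  stopifnot(n >= 1, f >= 0, f <= 1, all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-12) stop("frequencies must sum to 1")
  K <- length(freqs)
  alleles <- alleles %||% names(freqs) %||% format_allele_name(locus, seq_len(K), 1L)
  stopifnot(length(alleles) == K)
  set.seed(derive_seed(seed, paste0("gt", population, locus)))
  hom <- stats::runif(n) < f
  a1 <- sample.int(K, n, replace = TRUE, prob = freqs)
  a2 <- ifelse(hom, a1, sample.int(K, n, replace = TRUE, prob = freqs))
  pair <- cbind(alleles[pmin(a1, a2)], alleles[pmax(a1, a2)])
  tibble::tibble(
    individual = sprintf("%s_%04d", population, seq_len(n)),
    population = population,
    group = group,
    sex = sample(c("F", "M"), n, replace = TRUE),
    locus = locus,
    allele1 = pair[, 1],
    allele2 = pair[, 2]
  )
}

#' Default primer pools for the synthetic amplicon design
#'
#' Three UBA forward primers partition the alpha-1 lineages (F1: I, II, V,
#' VI; F2: III, VII; F3: IV, VIII) and share one reverse primer; DAA and DAB
#' each use a single forward/reverse pair that amplifies all alleles.
#'
#' @param loci Loci to include.
#' @return Primer tibble (`pool`, `locus`, `forward`, `reverse`, `lineages`
#'   list-column).
#' @export
default_primers <- function(loci = c("UBA", "DAA", "DAB")) {
  pr <- tibble::tribble(
    ~pool,    ~locus, ~forward,               ~reverse,               ~lin,
    "UBA.F1", "UBA",  "ACGTTGGCCAATCGATGCTA", "CCATGATCGTACGGTTAGCA", "I|II|V|VI",
    "UBA.F2", "UBA",  "TGCATCGGATTACCGGTACA", "CCATGATCGTACGGTTAGCA", "III|VII",
    "UBA.F3", "UBA",  "GATCCATGGCTTAGCACGTT", "CCATGATCGTACGGTTAGCA", "IV|VIII",
    "DAA.F",  "DAA",  "TTGACGCTAGCATCCGGATA", "AGGCTTACGATCGTGCAATC", "",
    "DAB.F",  "DAB",  "CAGTTCGGATACGCTAGGTA", "GTCAAGCTTGCACGGATTCA", ""
  )
  pr <- pr[pr$locus %in% loci, ]
  pr$lineages <- strsplit(pr$lin, "|", fixed = TRUE)
  validate_primers(pr[, c("pool", "locus", "forward", "reverse", "lineages")])
}

pool_for_allele <- function(locus, lineage, primers) {
  cand <- primers[primers$locus == locus, ]
  if (locus != "UBA") {
    if (nrow(cand) != 1) stop("expected one primer pool for ", locus)
    return(cand$pool)
  }
  hit <- vapply(cand$lineages, function(l) lineage %in% l, logical(1))
  if (sum(hit) != 1) {
    stop("allele lineage ", lineage, " served by ", sum(hit),
         " UBA pools; each allele must be amplifiable by exactly one pool")
  }
  cand$pool[hit]
}

# Inject i.i.d. substitution errors into m copies of a template and build
# quality strings. "informative" marks miscalled bases with low Phred scores
# (as base callers do); "constant" writes one flat score matching error_rate.
sim_read_copies <- function(template, m, error_rate, quality) {
  L <- nchar(template)
  tc <- chars(template)
  mat <- matrix(rep(tc, each = m), nrow = m)
  err <- matrix(stats::runif(m * L) < error_rate, nrow = m)
  qflat <- if (error_rate > 0) round(-10 * log10(error_rate)) else 40L
  if (any(err)) {
    idx <- which(err)
    mat[idx] <- vapply(mat[idx], function(b) sample(setdiff(BASES, b), 1),
                       character(1))
  }
  qmat <- matrix(40L, nrow = m, ncol = L)
  if (quality == "informative") {
    qmat[] <- sample(33:40, m * L, replace = TRUE)
    if (any(err)) qmat[which(err)] <- sample(5:15, sum(err), replace = TRUE)
  } else {
    qmat[] <- as.integer(qflat)
  }
  list(
    seq = apply(mat, 1, paste, collapse = ""),
    qual = apply(qmat, 1, function(q) phred_char(q))
  )
}

#' Simulate paired amplicon reads from genotypes
#'
#' Each amplicon is forward primer + allele template + reverse-complemented
#' reverse primer; read 1 and read 2 are the two `read_length`-nt ends (read
#' 2 reverse-complemented), carrying i.i.d. substitution errors. Reads from
#' a heterozygote split between the two alleles binomially. A truth manifest
#' records per-allele read counts for exact end-to-end checking.
#'
#' Per-individual random streams are derived by hashing individual IDs from
#' the one `seed`, so any subset of individuals is reproducible.
#'
#' @param genotypes Long genotype tibble (allele names must exist in
#'   `library`).
#' @param library Allele library tibble with `lineage` set for UBA.
#' @param primers Primer tibble (see [default_primers()]).
#' @param depth Read pairs per individual and locus.
#' @param read_length Read length in nt (Illumina-style 300 by default).
#' @param error_rate Substitution probability per base, in \[0, 0.5).
#' @param quality `"informative"` (default) or `"constant"`; see Details.
#' @param seed Integer seed.
#' @return List with `reads` (tibble: `individual`, `locus`, `pool`,
#'   `read1`, `read2`, `qual1`, `qual2`) and `truth` (tibble: `individual`,
#'   `locus`, `allele1`, `allele2`, `reads1`, `reads2`, `unmergeable`).
#' @export
sim_reads <- function(genotypes, library, primers = default_primers(),
                      depth = 500, read_length = 300, error_rate = 0.01,
                      quality = c("informative", "constant"), seed = 1) {
  quality <- match.arg(quality)
  stopifnot(error_rate >= 0, error_rate < 0.5)
  if (read_length < max(nchar(primers$forward)) + 20) {
    stop("read_length must be at least primer length + 20")
  }
  lib <- library
  miss <- setdiff(unique(c(genotypes$allele1, genotypes$allele2)), lib$name)
  if (length(miss) > 0) stop("alleles not in library: ", paste(miss, collapse = ", "))

  prim <- primers
  rows <- split(genotypes, seq_len(nrow(genotypes)))
  out_reads <- vector("list", length(rows))
  out_truth <- vector("list", length(rows))

  for (k in seq_along(rows)) {
    g <- rows[[k]]
    set.seed(derive_seed(seed, paste0(g$individual, ":", g$locus)))
    n1 <- if (g$allele1 == g$allele2) depth else stats::rbinom(1, depth, 0.5)
    counts <- c(n1, depth - n1)
    if (g$allele1 == g$allele2) counts <- c(depth, 0L)
    alleles <- c(g$allele1, g$allele2)
    per_allele <- vector("list", 2)
    unmergeable <- FALSE
    for (j in 1:2) {
      m <- counts[j]
      if (m == 0) next
      rec <- lib[match(alleles[j], lib$name), ]
      pool <- pool_for_allele(g$locus, rec$lineage, prim)
      pr <- prim[prim$pool == pool, ]
      amplicon <- paste0(pr$forward, rec$sequence, revcomp(pr$reverse))
      if (nchar(amplicon) > 2 * read_length - 10) unmergeable <- TRUE
      t1 <- substr(amplicon, 1, min(nchar(amplicon), read_length))
      t2 <- substr(revcomp(amplicon), 1, min(nchar(amplicon), read_length))
      r1 <- sim_read_copies(t1, m, error_rate, quality)
      r2 <- sim_read_copies(t2, m, error_rate, quality)
      per_allele[[j]] <- tibble::tibble(
        individual = g$individual, locus = g$locus, pool = pool,
        read1 = r1$seq, read2 = r2$seq, qual1 = r1$qual, qual2 = r2$qual
      )
    }
    out_reads[[k]] <- dplyr::bind_rows(per_allele)
    out_truth[[k]] <- tibble::tibble(
      individual = g$individual, locus = g$locus,
      allele1 = g$allele1, allele2 = g$allele2,
      reads1 = counts[1], reads2 = counts[2], unmergeable = unmergeable
    )
  }
  list(reads = dplyr::bind_rows(out_reads), truth = dplyr::bind_rows(out_truth))
}
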