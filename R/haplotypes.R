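# Parsimony phasing of unphased DAA-DAB two-locus genotypes into
# co-segregating haplotypes, plus consistency flagging.

hap_key <- function(daa, dab) paste(daa, dab, sep = "~")

#' Infer DAA-DAB haplotypes from unphased genotypes
#'
#' Clark-style parsimony phasing: (1) individuals homozygous at one or both
#' loci are unambiguous and seed the known-haplotype set; (2) double
#' heterozygotes whose two candidate phasings are separated by the known set
#' (one phasing contains a known haplotype, the other none) are resolved
#' iteratively; (3) the remainder are resolved towards the phasing with the
#' higher total known-haplotype count (most-frequent-haplotype parsimony)
#' and flagged `inferred`. The procedure is deterministic given table order;
#' residual ties are broken by haplotype name.
#'
#' @param genotypes Long genotype tibble containing `DAA` and `DAB` rows.
#'   Individuals missing either locus are excluded and reported.
#' @return List: `haplotypes` (tibble `daa`, `dab`, `count`), `phasing`
#'   (per-individual tibble with both haplotypes and the resolution
#'   `method`: `obligate`, `implied` or `inferred`), `excluded` (individual
#'   IDs without both loci called).
#' @export
infer_haplotypes <- function(genotypes) {
  gt <- genotypes %>%
    dplyr::filter(.data$locus %in% c("DAA", "DAB"),
                  !is.na(.data$allele1), !is.na(.data$allele2))
  wide <- gt %>%
    dplyr::select("individual", "locus", "allele1", "allele2") %>%
    tidyr::pivot_wider(names_from = "locus",
                       values_from = c("allele1", "allele2"))
  need <- c("allele1_DAA", "allele2_DAA", "allele1_DAB", "allele2_DAB")
  for (col in setdiff(need, names(wide))) wide[[col]] <- NA_character_
  complete <- stats::complete.cases(wide[need])
  excluded <- wide$individual[!complete]
  wide <- wide[complete, ]

  known <- new.env(parent = emptyenv())
  bump <- function(k) assign(k, (get0(k, known) %||% 0) + 1, envir = known)
  kcount <- function(k) get0(k, known) %||% 0

  phase <- vector("list", nrow(wide))
  # stage 1: homozygote anchoring (obligate phase)
  unresolved <- integer(0)
  for (i in seq_len(nrow(wide))) {
    a <- c(wide$allele1_DAA[i], wide$allele2_DAA[i])
    b <- c(wide$allele1_DAB[i], wide$allele2_DAB[i])
    if (a[1] == a[2] || b[1] == b[2]) {
      h <- c(hap_key(a[1], b[1]), hap_key(a[2], b[2]))
      bump(h[1]); bump(h[2])
      phase[[i]] <- tibble::tibble(individual = wide$individual[i],
                                   hap1 = h[1], hap2 = h[2],
                                   method = "obligate")
    } else {
      unresolved <- c(unresolved, i)
    }
  }

  phasings <- function(i) {
    a <- c(wide$allele1_DAA[i], wide$allele2_DAA[i])
    b <- c(wide$allele1_DAB[i], wide$allele2_DAB[i])
    list(cis = c(hap_key(a[1], b[1]), hap_key(a[2], b[2])),
         trans = c(hap_key(a[1], b[2]), hap_key(a[2], b[1])))
  }

  # stage 2: phases implied by the known set, to a fixed point
  repeat {
    progressed <- FALSE
    still <- integer(0)
    for (i in unresolved) {
      ph <- phasings(i)
      n_cis <- sum(vapply(ph$cis, kcount, numeric(1)) > 0)
      n_trans <- sum(vapply(ph$trans, kcount, numeric(1)) > 0)
      if ((n_cis > 0) != (n_trans > 0)) {
        h <- if (n_cis > 0) ph$cis else ph$trans
        bump(h[1]); bump(h[2])
        phase[[i]] <- tibble::tibble(individual = wide$individual[i],
                                     hap1 = h[1], hap2 = h[2],
                                     method = "implied")
        progressed <- TRUE
      } else {
        still <- c(still, i)
      }
    }
    unresolved <- still
    if (!progressed || length(unresolved) == 0) break
  }

  # stage 3: most-frequent-haplotype parsimony, ties by haplotype name
  for (i in unresolved) {
    ph <- phasings(i)
    w_cis <- sum(vapply(ph$cis, kcount, numeric(1)))
    w_trans <- sum(vapply(ph$trans, kcount, numeric(1)))
    h <- if (w_cis > w_trans) ph$cis
         else if (w_trans > w_cis) ph$trans
         else if (paste(sort(ph$cis), collapse = "|") <=
                  paste(sort(ph$trans), collapse = "|")) ph$cis
         else ph$trans
    bump(h[1]); bump(h[2])
    phase[[i]] <- tibble::tibble(individual = wide$individual[i],
                                 hap1 = h[1], hap2 = h[2],
                                 method = "inferred")
  }

  phasing <- dplyr::bind_rows(phase)
  haplotypes <- if (nrow(phasing) > 0) {
    tibble::tibble(key = c(phasing$hap1, phasing$hap2)) %>%
      dplyr::count(.data$key, name = "count") %>%
      tidyr::separate_wider_delim("key", "~", names = c("daa", "dab")) %>%
      dplyr::arrange(.data$daa, .data$dab)
  } else {
    tibble::tibble(daa = character(0), dab = character(0), count = integer(0))
  }
  list(haplotypes = haplotypes, phasing = phasing, excluded = excluded)
}

#' Flag inconsistently segregating haplotypes
#'
#' Haplotype combinations seen in a single copy are flagged `singleton`
#' (possible typing artifacts). An allele at either locus that appears in
#' two or more haplotypes each supported by at least two copies is flagged
#' `conflicting`; when peptides are supplied the amino-acid distance between
#' the alternative partner alleles is annotated (`point_mutation` at 1 aa,
#' `recombination_conversion` beyond, the signature of recombination or gene
#' conversion between the closely linked genes).
#'
#' @param haplotypes Haplotype tibble (`daa`, `dab`, `count`) from
#'   [infer_haplotypes()].
#' @param library Optional allele library with `name` and `peptide`, used
#'   for the partner amino-acid distances.
#' @return The tibble with `status` (`consistent`, `singleton`,
#'   `conflicting`) and `annotation` columns.
#' @export
flag_haplotype_conflicts <- function(haplotypes, library = NULL) {
  hp <- haplotypes %>%
    dplyr::mutate(status = ifelse(.data$count == 1, "singleton", "consistent"),
                  annotation = NA_character_)

  aa_dist <- function(n1, n2) {
    if (is.null(library)) return(NA_integer_)
    p1 <- library$peptide[match(n1, library$name)]
    p2 <- library$peptide[match(n2, library$name)]
    if (is.na(p1) || is.na(p2)) return(NA_integer_)
    aln <- align_local(p1, p2, type = "protein")
    as.integer(aln$columns - aln$matches)
  }

  flag_side <- function(hp, shared, partner) {
    solid <- hp[hp$count >= 2, ]
    multi <- solid %>%
      dplyr::count(.data[[shared]], name = "n_partners") %>%
      dplyr::filter(.data$n_partners >= 2)
    for (al in multi[[shared]]) {
      idx <- which(hp[[shared]] == al & hp$count >= 2)
      partners <- hp[[partner]][idx]
      d <- utils::combn(partners, 2, function(pr) aa_dist(pr[1], pr[2]))
      dmax <- suppressWarnings(max(d, na.rm = TRUE))
      ann <- if (!is.finite(dmax)) NA_character_
             else if (dmax == 1) "point_mutation"
             else "recombination_conversion"
      hp$status[idx] <- "conflicting"
      hp$annotation[idx] <- ifelse(is.na(ann), hp$annotation[idx],
                                   paste0(shared, ":", al, " partners ",
                                          dmax, "aa (", ann, ")"))
    }
    hp
  }
  hp <- flag_side(hp, "dab", "daa")
  hp <- flag_side(hp, "daa", "dab")
  hp
}

#' Cross-check DAA allelic richness against DAB-linked haplotypes
#'
#' Because DAA and DAB segregate as haplotypes, DAA allelic richness
#' computed from DAB-linked haplotype copies should match the directly
#' computed value; this reports both for a given rarefaction size.
#'
#' @param genotypes Long genotype tibble with DAA and DAB rows.
#' @param g Rarefaction size in allele copies.
#' @return Tibble with `source` (`direct`, `haplotype_linked`) and `ar`.
#' @export
daa_richness_crosscheck <- function(genotypes, g = 34) {
  direct <- genotypes %>%
    dplyr::filter(.data$locus == "DAA", !is.na(.data$allele1), !is.na(.data$allele2))
  counts_direct <- table(c(direct$allele1, direct$allele2))
  hp <- infer_haplotypes(genotypes)
  counts_hap <- tapply(hp$haplotypes$count, hp$haplotypes$daa, sum)
  tibble::tibble(
    source = c("direct", "haplotype_linked"),
    ar = c(allelic_richness(as.integer(counts_direct), g),
           allelic_richness(as.integer(counts_hap), g))
  )
}
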