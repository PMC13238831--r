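# Classification of candidate allele sequences against a reference library,
# IPD-style name assignment by amino-acid distance, and alpha-1 lineage
# assignment by Jukes-Cantor nearest reference.

#' Smith-Waterman local alignment with identity and similarity
#'
#' Optimal local alignment via [Biostrings::pairwiseAlignment()] with the
#' EMBOSS Water defaults: nucleotide match +5 / mismatch -4, protein
#' BLOSUM62, gap open 10 and gap extend 0.5. Identity is
#' matches / alignment columns (gap columns included); for proteins,
#' similarity additionally counts positive-scoring substitutions.
#'
#' @param query Single sequence (character).
#' @param targets Character vector of sequences to align against.
#' @param type `"nucleotide"` or `"protein"`.
#' @return Tibble, one row per target: `target`, `score`, `columns`,
#'   `matches`, `identity`, `similarity`, `aligned_query`, `aligned_target`.
#' @export
align_local <- function(query, targets, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  stopifnot(nchar(query) > 0, all(nchar(targets) > 0))
  if (type == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = TRUE)
    pat <- Biostrings::DNAStringSet(targets)
    sub <- Biostrings::DNAString(query)
  } else {
    mat <- blosum62()
    pat <- Biostrings::AAStringSet(targets)
    sub <- Biostrings::AAString(query)
  }
  aln <- Biostrings::pairwiseAlignment(pat, sub, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 0.5)
  at <- as.character(Biostrings::pattern(aln))
  aq <- as.character(Biostrings::subject(aln))
  stats <- purrr::map2(aq, at, function(x, y) {
    cx <- chars(x); cy <- chars(y)
    cols <- length(cx)
    match_pos <- cx == cy & cx != "-"
    sim <- if (type == "protein") {
      ok <- cx != "-" & cy != "-"
      pos <- sum(mat[cbind(cx[ok], cy[ok])] > 0)
      pos
    } else {
      sum(match_pos)
    }
    c(cols = cols, matches = sum(match_pos), sim = sim)
  })
  st <- do.call(rbind, stats)
  tibble::tibble(
    target = targets,
    score = Biostrings::score(aln),
    columns = as.integer(st[, "cols"]),
    matches = as.integer(st[, "matches"]),
    identity = unname(100 * st[, "matches"] / st[, "cols"]),
    similarity = unname(100 * st[, "sim"] / st[, "cols"]),
    aligned_query = aq,
    aligned_target = at
  )
}

#' Find the closest reference allele for a query sequence
#'
#' References are ranked by nucleotide identity; ties are broken by
#' amino-acid identity, then lexicographically by name. The amino-acid
#' difference count (`aa_diff`: substitutions plus gap columns over the
#' aligned peptide region) drives the naming rules in
#' [assign_allele_name()].
#'
#' @param query Nucleotide sequence.
#' @param library Allele library tibble (same locus).
#' @param query_peptide Optional; computed with [adjust_reading_frame()]
#'   when absent.
#' @return One-row tibble (match report): `query`, `reference`,
#'   `nt_identity`, `aa_identity`, `aa_diff`, `nt_identical`,
#'   `longer_identical`.
#' @export
closest_reference <- function(query, library, query_peptide = NULL) {
  stopifnot(nrow(library) > 0)
  if (is.null(query_peptide)) {
    fr <- adjust_reading_frame(query)
    query_peptide <- if (is.na(fr$peptide[1])) translate_nt(query) else fr$peptide[1]
  }
  nt <- align_local(query, library$sequence, type = "nucleotide")
  best_nt <- max(nt$identity)
  cand <- which(nt$identity >= best_nt - 1e-9)
  aa_stats <- function(i) {
    aa <- align_local(query_peptide, library$peptide[i], type = "protein")
    c(identity = aa$identity, diff = aa$columns - aa$matches)
  }
  aa <- vapply(cand, aa_stats, c(identity = 0, diff = 0))
  ord <- order(-aa["identity", ], library$name[cand])
  pick <- cand[ord[1]]
  aapick <- aa[, ord[1]]
  ref <- library[pick, ]
  tibble::tibble(
    query = query,
    reference = ref$name,
    nt_identity = nt$identity[pick],
    aa_identity = unname(aapick["identity"]),
    aa_diff = as.integer(aapick["diff"]),
    nt_identical = identical(query, ref$sequence),
    longer_identical = nchar(query) > nchar(ref$sequence) &&
      grepl(ref$sequence, query, fixed = TRUE)
  )
}

aa_threshold <- function(locus) if (locus == "UBA") 4L else 3L

#' Assign an IPD-style name to a candidate allele
#'
#' Decision table (T = 4 amino acids for UBA, 3 for DAA/DAB, matching the
#' standing nomenclature): identical nucleotide sequence keeps the existing
#' name; a synonymous variant (0 aa difference, different nucleotides) gets
#' a six-digit extension of the matched allele; 0 < aa_diff <= T gets a new
#' four-digit number inside the matched two-digit family; aa_diff > T founds
#' a new two-digit family; a longer sequence identical over the matched span
#' gets the `_L` suffix (same allele for all statistics).
#'
#' New numbers are allocated first-come; classify candidates in a
#' reproducible order (see [classify_alleles()]).
#'
#' @param query Nucleotide sequence.
#' @param locus Locus of the query.
#' @param library Allele library tibble (acts as the name registry).
#' @param query_peptide Optional peptide (frame-adjusted).
#' @return List: `record` (one-row allele tibble, `novel` flags new
#'   entries), `library` (with the record appended when novel), `report`
#'   (match report with a `decision` column).
#' @export
assign_allele_name <- function(query, locus, library, query_peptide = NULL) {
  lib <- library[library$locus == locus, ]
  stopifnot(nrow(lib) > 0)
  rep <- closest_reference(query, lib, query_peptide)
  refrow <- lib[match(rep$reference, lib$name), ]

  new_record <- function(f1, f2, f3, suffix, decision) {
    name <- format_allele_name(locus, f1, f2, f3, suffix)
    if (name %in% library$name) {
      stop("registry collision: ", name, " already taken (corrupt registry)")
    }
    fr <- adjust_reading_frame(query)
    tibble::tibble(
      name = name, locus = locus, field1 = as.integer(f1),
      field2 = as.integer(f2), field3 = as.integer(f3),
      suffix = if (is.na(suffix)) NA_character_ else suffix,
      sequence = query,
      peptide = if (!is.na(fr$peptide[1])) fr$peptide[1] else translate_nt(query),
      lineage = NA_character_, novel = TRUE
    )
  }

  if (rep$nt_identical) {
    rec <- refrow[, c("name", "locus", "field1", "field2", "field3", "suffix",
                      "sequence", "peptide", "lineage", "novel")]
    rec$novel <- FALSE
    decision <- "existing"
    out_lib <- library
  } else if (rep$longer_identical) {
    decision <- "long_variant"
    rec <- new_record(refrow$field1, refrow$field2, refrow$field3, "_L", decision)
    out_lib <- dplyr::bind_rows(library, rec)
  } else if (rep$aa_diff == 0) {
    sibs <- lib[lib$field1 == refrow$field1 & lib$field2 == refrow$field2, ]
    f3 <- if (all(is.na(sibs$field3))) 2L else max(sibs$field3, na.rm = TRUE) + 1L
    decision <- "synonymous_extension"
    rec <- new_record(refrow$field1, refrow$field2, f3, NA, decision)
    out_lib <- dplyr::bind_rows(library, rec)
  } else if (rep$aa_diff <= aa_threshold(locus)) {
    f2 <- max(lib$field2[lib$field1 == refrow$field1]) + 1L
    decision <- "new_protein_variant"
    rec <- new_record(refrow$field1, f2, NA, NA, decision)
    out_lib <- dplyr::bind_rows(library, rec)
  } else {
    f1 <- max(lib$field1) + 1L
    decision <- "new_family"
    rec <- new_record(f1, 1L, NA, NA, decision)
    out_lib <- dplyr::bind_rows(library, rec)
  }
  rep$decision <- decision
  list(record = rec, library = out_lib, report = rep)
}

#' Classify a batch of candidate sequences against a library
#'
#' Candidates are processed in decreasing order of read support (ties by
#' sequence) so that number allocation is reproducible; identical sequences
#' seen twice resolve to the same name (naming is idempotent). Exact library
#' matches short-circuit the alignment machinery.
#'
#' @param candidates Tibble with `sequence`, `locus` and optionally
#'   `support` (total read support; defaults to 1).
#' @param library Allele library tibble.
#' @return List: `map` (tibble `sequence`, `locus`, `name`, `novel`,
#'   `decision`), `library` (updated with novel records appended).
#' @export
classify_alleles <- function(candidates, library) {
  cand <- tibble::as_tibble(candidates)
  if (!"support" %in% names(cand)) cand$support <- 1
  agg <- cand %>%
    dplyr::group_by(.data$locus, .data$sequence) %>%
    dplyr::summarise(support = sum(.data$support), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$sequence)
  lib <- library
  rows <- vector("list", nrow(agg))
  for (i in seq_len(nrow(agg))) {
    sq <- agg$sequence[i]
    lc <- agg$locus[i]
    hit <- which(lib$locus == lc & lib$sequence == sq)
    if (length(hit) > 0) {
      rows[[i]] <- tibble::tibble(sequence = sq, locus = lc,
                                  name = lib$name[hit[1]],
                                  novel = FALSE, decision = "existing")
    } else {
      res <- assign_allele_name(sq, lc, lib)
      lib <- res$library
      rows[[i]] <- tibble::tibble(sequence = sq, locus = lc,
                                  name = res$record$name,
                                  novel = res$record$novel,
                                  decision = res$report$decision)
    }
  }
  list(map = dplyr::bind_rows(rows), library = lib)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' \eqn{d = -\frac{3}{4} \ln(1 - \frac{4p}{3})} where `p` is the proportion
#' of differing ungapped columns. Saturated pairs (`p >= 0.75`) return `NA`.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (may contain
#'   `-` gap characters; gap columns are dropped).
#' @param min_sites Minimum ungapped columns required.
#' @return Distance (substitutions per site) or `NA` on saturation.
#' @export
jc_distance <- function(aligned_a, aligned_b, min_sites = 50) {
  ca <- chars(aligned_a)
  cb <- chars(aligned_b)
  stopifnot(length(ca) == length(cb))
  ok <- ca != "-" & cb != "-"
  if (sum(ok) < min_sites) {
    stop("need at least ", min_sites, " ungapped aligned columns")
  }
  p <- mean(ca[ok] != cb[ok])
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Exemplar alpha-1 sequences per lineage from a library
#'
#' @param library UBA allele library with `lineage` and `alpha1` (or full
#'   `sequence`) columns.
#' @return Tibble `lineage`, `sequence` (one exemplar per lineage).
#' @export
lineage_exemplars <- function(library) {
  lib <- library[!is.na(library$lineage), ]
  stopifnot(nrow(lib) > 0)
  seqs <- if ("alpha1" %in% names(lib) && !all(is.na(lib$alpha1))) {
    lib$alpha1
  } else {
    substr(lib$sequence, 1, UBA_ALPHA1_NT)
  }
  tibble::tibble(lineage = lib$lineage, sequence = seqs) %>%
    dplyr::distinct(.data$lineage, .keep_all = TRUE)
}

#' Assign a UBA alpha-1 lineage by nearest Jukes-Cantor reference
#'
#' The query (full allele or alpha-1 fragment) is locally aligned to one
#' exemplar alpha-1 per lineage (which extracts the alpha-1 region), and the
#' lineage of the Jukes-Cantor-nearest exemplar is returned. A margin
#' (second-best minus best distance) below 0.01 flags the call ambiguous;
#' saturation against every exemplar leaves it unassigned.
#'
#' @param query Nucleotide sequence.
#' @param exemplars Tibble `lineage`, `sequence` (see [lineage_exemplars()]).
#' @param margin_min Ambiguity margin threshold.
#' @return One-row tibble: `lineage` (`NA` if unassigned), `distance`,
#'   `margin`, `ambiguous`.
#' @export
assign_lineage <- function(query, exemplars, margin_min = 0.01) {
  aln <- align_local(query, exemplars$sequence, type = "nucleotide")
  d <- purrr::map2_dbl(aln$aligned_query, aln$aligned_target, function(x, y) {
    tryCatch(jc_distance(x, y), error = function(e) NA_real_)
  })
  if (all(is.na(d))) {
    return(tibble::tibble(lineage = NA_character_, distance = NA_real_,
                          margin = NA_real_, ambiguous = NA))
  }
  ord <- order(d)
  best <- ord[1]
  margin <- if (sum(!is.na(d)) >= 2) d[ord[2]] - d[best] else Inf
  tibble::tibble(
    lineage = exemplars$lineage[best],
    distance = d[best],
    margin = margin,
    ambiguous = margin < margin_min
  )
}
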