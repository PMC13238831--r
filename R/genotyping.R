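# Per-individual amplicon genotyping: quality filter -> primer demultiplex
# -> pair merging -> exact collapse -> top-candidate selection -> reading
# frame adjustment -> <= 2 allele calls per locus.

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || nchar(q) == 0) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Quality-filter read pairs
#'
#' Drops pairs where either read has mean Phred quality below `min_mean_q`
#' or length below `min_length`.
#'
#' @param reads Paired-read tibble (`read1`, `read2`, `qual1`, `qual2`).
#' @param min_mean_q Minimum mean Phred score per read.
#' @param min_length Minimum read length.
#' @return Filtered tibble; the number of dropped pairs is in
#'   `attr(, "dropped")`.
#' @export
filter_read_pairs <- function(reads, min_mean_q = 20, min_length = 50) {
  keep <- nchar(reads$read1) >= min_length & nchar(reads$read2) >= min_length &
    mean_phred(reads$qual1) >= min_mean_q & mean_phred(reads$qual2) >= min_mean_q
  out <- reads[keep, ]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Demultiplex read pairs by primer with zero mismatches
#'
#' A pair is assigned to a pool iff read 1 begins exactly with the pool's
#' forward primer and read 2 begins exactly with its reverse primer; primers
#' are then stripped. Any mismatch leaves the pair unassigned (`pool = NA`,
#' sequences unstripped). A pair matching two pools signals a malformed pool
#' configuration and is an error.
#'
#' @param reads Paired-read tibble.
#' @param primers Primer tibble (see [default_primers()], [read_primers()]).
#' @return The tibble with a `pool` column; assigned rows are
#'   primer-stripped.
#' @export
demultiplex_reads <- function(reads, primers) {
  validate_primers(primers)
  n <- nrow(reads)
  pool <- rep(NA_character_, n)
  if (n > 0) {
    hits <- matrix(FALSE, n, nrow(primers))
    for (k in seq_len(nrow(primers))) {
      hits[, k] <- startsWith(reads$read1, primers$forward[k]) &
        startsWith(reads$read2, primers$reverse[k])
    }
    multi <- rowSums(hits) > 1
    if (any(multi)) {
      stop(sum(multi), " read pair(s) match more than one pool: ",
           "malformed pool configuration")
    }
    hit_idx <- apply(hits, 1, function(z) if (any(z)) which(z) else NA_integer_)
    assigned <- !is.na(hit_idx)
    pool[assigned] <- primers$pool[hit_idx[assigned]]
    fl <- nchar(primers$forward)[hit_idx[assigned]]
    rl <- nchar(primers$reverse)[hit_idx[assigned]]
    reads$read1[assigned] <- substr(reads$read1[assigned], fl + 1L,
                                    nchar(reads$read1[assigned]))
    reads$read2[assigned] <- substr(reads$read2[assigned], rl + 1L,
                                    nchar(reads$read2[assigned]))
    if (all(c("qual1", "qual2") %in% names(reads))) {
      reads$qual1[assigned] <- substr(reads$qual1[assigned], fl + 1L,
                                      nchar(reads$qual1[assigned]))
      reads$qual2[assigned] <- substr(reads$qual2[assigned], rl + 1L,
                                      nchar(reads$qual2[assigned]))
    }
  }
  reads$pool <- pool
  reads
}

#' Merge overlapping read pairs
#'
#' Reverse-complements read 2 and chooses the overlap length maximizing
#' matches among overlaps of at least `min_overlap` bases whose mismatch
#' density does not exceed `max_mismatch_density` (ties favour the longer
#' overlap). Disagreeing overlap bases take the higher-quality call (ties
#' take read 1). Pairs with no admissible overlap get `merged = NA` and are
#' excluded from collapsing.
#'
#' @param reads Paired-read tibble (primer-stripped).
#' @inheritParams genotype_amplicons
#' @return The tibble with a `merged` column.
#' @export
merge_read_pairs <- function(reads, min_overlap = 10, max_mismatch_density = 0.25) {
  q1 <- reads$qual1 %||% strrep("I", nchar(reads$read1))
  q2 <- reads$qual2 %||% strrep("I", nchar(reads$read2))
  q1[is.na(q1)] <- strrep("I", nchar(reads$read1[is.na(q1)]))
  q2[is.na(q2)] <- strrep("I", nchar(reads$read2[is.na(q2)]))
  reads$merged <- merge_pairs_cpp(reads$read1, reads$read2, q1, q2,
                                  as.integer(min_overlap), max_mismatch_density)
  reads
}

#' Collapse merged reads into ranked unique sequences
#'
#' Exact-string grouping; output sorted by decreasing count with ties broken
#' lexicographically, so ranking is deterministic.
#'
#' @param sequences Character vector of merged sequences (`NA` ignored).
#' @return Tibble `sequence`, `count`, ordered; total input count in
#'   `attr(, "total")`.
#' @export
collapse_reads <- function(sequences) {
  sequences <- sequences[!is.na(sequences)]
  out <- tibble::tibble(sequence = sequences) %>%
    dplyr::count(.data$sequence, name = "count") %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  attr(out, "total") <- length(sequences)
  out
}

#' Select top candidate alleles from a collapsed read set
#'
#' Keeps the `top_n` highest-count sequences whose count is at least
#' `min_frac` of the merged-read total for the pool.
#'
#' @param candidates Tibble `sequence`, `count` (from [collapse_reads()]).
#' @param top_n Maximum number of candidates retained.
#' @param min_frac Minimum count fraction of the merged total.
#' @param total Merged-read total; defaults to `attr(candidates, "total")`
#'   or the column sum.
#' @return Filtered candidate tibble (possibly empty).
#' @export
select_candidates <- function(candidates, top_n = 5, min_frac = 0.01,
                              total = NULL) {
  total <- total %||% attr(candidates, "total") %||% sum(candidates$count)
  if (is.null(total) || total == 0) {
    return(candidates[0, ])
  }
  candidates %>%
    dplyr::filter(.data$count / total >= min_frac) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) %>%
    utils::head(top_n)
}

#' Adjust reading frame by end-trimming 0-2 nucleotides
#'
#' Over the nine trim combinations (0-2 nt off each end) the one whose
#' frame-0 translation has no internal stop codon and the longest peptide is
#' chosen; ties take the smallest `(offset5, offset3)` lexicographically.
#' Sequences whose nine translations all contain internal stops are flagged
#' invalid (non-coding artifacts).
#'
#' @param sequences Character vector of nucleotide sequences (length >= 30).
#' @return Tibble, one row per input: `sequence`, `trimmed`, `offset5`,
#'   `offset3`, `peptide`, `valid`.
#' @export
adjust_reading_frame <- function(sequences) {
  stopifnot(all(nchar(sequences) >= 30))
  offs <- expand.grid(offset3 = 0:2, offset5 = 0:2)[, c("offset5", "offset3")]
  offs <- offs[order(offs$offset5, offs$offset3), ]
  n <- length(sequences)
  subs <- character(n * 9L)
  for (k in seq_len(9L)) {
    idx <- (k - 1L) * n + seq_len(n)
    subs[idx] <- substr(sequences, 1L + offs$offset5[k],
                        nchar(sequences) - offs$offset3[k])
  }
  peps <- translate_nt(subs)
  core <- sub("\\*$", "", peps)
  valid <- !grepl("*", core, fixed = TRUE)
  plen <- nchar(core)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- (seq_len(9L) - 1L) * n + i
    v <- valid[idx]
    if (!any(v)) {
      out[[i]] <- tibble::tibble(sequence = sequences[i], trimmed = NA_character_,
                                 offset5 = NA_integer_, offset3 = NA_integer_,
                                 peptide = NA_character_, valid = FALSE)
      next
    }
    lens <- ifelse(v, plen[idx], -1L)
    best <- which.max(lens)  # first maximum = smallest (offset5, offset3)
    out[[i]] <- tibble::tibble(
      sequence = sequences[i],
      trimmed = subs[idx[best]],
      offset5 = offs$offset5[best],
      offset3 = offs$offset3[best],
      peptide = core[idx[best]],
      valid = TRUE
    )
  }
  dplyr::bind_rows(out)
}

#' Call a diploid genotype from classified candidates
#'
#' Unifies candidates across primer pools by allele name, then keeps at most
#' two alleles per individual and locus: more than two distinct alleles keep
#' the two with highest read support (flag `excess_alleles`); one allele is
#' a homozygous call (flag `low_support` below `depth_floor` reads); none is
#' a missing genotype.
#'
#' @param assignments Tibble `individual`, `locus`, `name`, `support`.
#' @param depth_floor Minimum read support for a single-candidate
#'   homozygous call to go unflagged.
#' @return Genotype-call tibble: `individual`, `locus`, `allele1`,
#'   `allele2`, `support1`, `support2`, `flags` (`NA` or `;`-separated).
#' @export
call_genotypes <- function(assignments, depth_floor = 50) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(individual = character(0), locus = character(0),
                          allele1 = character(0), allele2 = character(0),
                          support1 = numeric(0), support2 = numeric(0),
                          flags = character(0)))
  }
  assignments %>%
    dplyr::group_by(.data$individual, .data$locus, .data$name) %>%
    dplyr::summarise(support = sum(.data$support), .groups = "drop_last") %>%
    dplyr::arrange(dplyr::desc(.data$support), .data$name, .by_group = TRUE) %>%
    dplyr::summarise(call = {
      nm <- .data$name
      sp <- .data$support
      flags <- character(0)
      if (length(nm) == 0) {
        a <- c(NA_character_, NA_character_); s <- c(NA_real_, NA_real_)
        flags <- "missing"
      } else if (length(nm) == 1) {
        a <- c(nm, nm); s <- c(sp, sp)
        if (sp < depth_floor) flags <- "low_support"
      } else {
        if (length(nm) > 2) flags <- "excess_alleles"
        a <- nm[1:2]; s <- sp[1:2]
        o <- order(a)
        a <- a[o]; s <- s[o]
      }
      list(tibble::tibble(allele1 = a[1], allele2 = a[2],
                          support1 = s[1], support2 = s[2],
                          flags = if (length(flags)) paste(flags, collapse = ";")
                                  else NA_character_))
    }, .groups = "drop") %>%
    tidyr::unnest("call")
}

#' Genotype individuals from paired amplicon reads
#'
#' End-to-end pipeline: quality filter, zero-mismatch primer demultiplexing,
#' overlap merging, exact collapsing, top-candidate selection (at least
#' `min_frac` of the pool's merged reads, at most `top_n`), reading-frame
#' adjustment, classification against the allele library (novel alleles are
#' named on the fly) and diploid genotype calling. Individuals whose pools
#' yield no admissible candidate are reported with a missing genotype.
#'
#' @param reads Paired-read tibble (`individual`, `read1`, `read2`, `qual1`,
#'   `qual2`), e.g. from [sim_reads()] or [read_fastq_pairs()].
#' @param primers Primer tibble.
#' @param library Allele reference library tibble.
#' @param top_n,min_frac Candidate selection thresholds.
#' @param depth_floor Support floor for unflagged homozygous calls.
#' @param min_mean_q,min_length Read quality filter.
#' @param min_overlap,max_mismatch_density Merge parameters.
#' @return List: `genotypes` (one row per individual x locus), `candidates`
#'   (selected candidate sequences with names), `library` (updated with any
#'   novel alleles), `stats` (read accounting: input, low-quality, assigned,
#'   unassigned, merged, unmerged).
#' @export
genotype_amplicons <- function(reads, primers, library, top_n = 5,
                               min_frac = 0.01, depth_floor = 50,
                               min_mean_q = 20, min_length = 50,
                               min_overlap = 10, max_mismatch_density = 0.25) {
  n_input <- nrow(reads)
  flt <- filter_read_pairs(reads, min_mean_q = min_mean_q, min_length = min_length)
  dmx <- demultiplex_reads(flt, primers)
  assigned <- dmx[!is.na(dmx$pool), ]
  mrg <- merge_read_pairs(assigned, min_overlap = min_overlap,
                          max_mismatch_density = max_mismatch_density)
  pool_locus <- stats::setNames(primers$locus, primers$pool)

  cand <- mrg %>%
    dplyr::filter(!is.na(.data$merged)) %>%
    dplyr::group_by(.data$individual, .data$pool) %>%
    dplyr::group_modify(function(df, key) {
      cs <- collapse_reads(df$merged)
      select_candidates(cs, top_n = top_n, min_frac = min_frac,
                        total = attr(cs, "total"))
    }) %>%
    dplyr::ungroup()

  if (nrow(cand) > 0) {
    fr <- adjust_reading_frame(cand$sequence)
    cand$trimmed <- fr$trimmed
    cand$peptide <- fr$peptide
    cand$valid <- fr$valid
    cand <- cand[cand$valid, ]
  }

  if (nrow(cand) > 0) {
    cand$locus <- unname(pool_locus[cand$pool])
    cls <- classify_alleles(
      tibble::tibble(sequence = cand$trimmed, locus = cand$locus,
                     support = cand$count),
      library
    )
    cand <- dplyr::left_join(
      cand,
      dplyr::rename(cls$map, trimmed = "sequence"),
      by = c("trimmed", "locus")
    )
    out_lib <- cls$library
  } else {
    cand$locus <- character(0)
    cand$name <- character(0)
    out_lib <- library
  }

  # every individual x locus attempted, so dropouts surface as missing
  frame <- tidyr::expand_grid(
    individual = unique(reads$individual),
    locus = unique(primers$locus)
  )
  calls <- call_genotypes(
    dplyr::select(cand, "individual", "locus", "name", support = "count"),
    depth_floor = depth_floor
  )
  genotypes <- frame %>%
    dplyr::left_join(calls, by = c("individual", "locus")) %>%
    dplyr::mutate(flags = ifelse(is.na(.data$allele1) & is.na(.data$flags),
                                 "missing", .data$flags))

  stats <- tibble::tibble(
    input_pairs = n_input,
    low_quality = attr(flt, "dropped"),
    assigned = sum(!is.na(dmx$pool)),
    unassigned = sum(is.na(dmx$pool)),
    merged = sum(!is.na(mrg$merged)),
    unmerged = sum(is.na(mrg$merged))
  )
  list(genotypes = genotypes, candidates = cand, library = out_lib,
       stats = stats)
}
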