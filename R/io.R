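#' Parse IPD-style MHC allele names
#'
#' Allele names follow the `Sasa-UBA*13:01` convention: an optional species
#' prefix, a three-letter locus, then colon-separated two-digit fields
#' (family, protein variant, optional synonymous variant) and an optional
#' suffix such as `_L` for a long variant of the same allele.
#'
#' @param x Character vector of allele names, with or without the `Sasa-`
#'   prefix (e.g. `"Sasa-UBA*13:01"`, `"DAB*09:01_L"`).
#' @return A tibble with one row per name: `name` (normalised, without
#'   species prefix), `locus`, `field1`, `field2`, `field3` (integer or `NA`),
#'   `suffix` (`NA` when absent).
#' @export
#' @examples
#' parse_allele_name(c("Sasa-UBA*13:01", "DAA*03:03:02", "DAB*09:01_L"))
parse_allele_name <- function(x) {
  rx <- "^(?:Sasa-)?([A-Z]{3})\\*(\\d{2,}):(\\d{2,})(?::(\\d{2,}))?(_[A-Za-z0-9]+)?$"
  m <- regmatches(x, regexec(rx, as.character(x)))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed allele name(s): ", paste(x[bad], collapse = ", "))
  }
  f <- function(i) vapply(m, `[`, character(1), i + 1L)
  tibble::tibble(
    locus = f(1),
    field1 = as.integer(f(2)),
    field2 = as.integer(f(3)),
    field3 = suppressWarnings(as.integer(ifelse(f(4) == "", NA, f(4)))),
    suffix = ifelse(f(5) == "", NA_character_, f(5))
  ) %>%
    dplyr::mutate(
      name = format_allele_name(.data$locus, .data$field1, .data$field2,
                                .data$field3, .data$suffix),
      .before = 1
    )
}

#' Format an allele name from its parts
#'
#' @param locus,field1,field2,field3,suffix Components as in
#'   [parse_allele_name()]; `field3`/`suffix` may be `NA`.
#' @return Character vector of names such as `"UBA*13:01"`.
#' @export
format_allele_name <- function(locus, field1, field2, field3 = NA, suffix = NA) {
  d2 <- function(v) sprintf("%02d", as.integer(v))
  out <- paste0(locus, "*", d2(field1), ":", d2(field2))
  has3 <- !is.na(field3)
  out[has3] <- paste0(out[has3], ":", d2(field3[has3]))
  hass <- !is.na(suffix)
  out[hass] <- paste0(out[hass], suffix[hass])
  out
}

#' Read an allele reference library from FASTA
#'
#' Headers must carry IPD-style names (`Sasa-UBA*13:01`). Sequences are
#' translated in frame 0 to the peptide used by the naming rules.
#'
#' @param path FASTA file.
#' @return Allele library tibble: `name`, `locus`, `field1`, `field2`,
#'   `field3`, `suffix`, `sequence`, `peptide`, `lineage` (`NA`; alpha-1
#'   lineage labels for UBA can be attached with [assign_lineage()]),
#'   `novel` (`FALSE` for library records).
#' @export
read_allele_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  info <- tryCatch(parse_allele_name(hdr), error = function(e) {
    stop("in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  info %>%
    dplyr::mutate(
      sequence = unname(as.character(ss)),
      peptide = translate_nt(.data$sequence),
      lineage = NA_character_,
      novel = FALSE
    )
}

#' Write an allele library to FASTA
#'
#' @param library Allele library tibble (see [read_allele_fasta()]).
#' @param path Output file.
#' @param prefix Species prefix prepended to each name.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(library, path, prefix = "Sasa-") {
  ss <- Biostrings::DNAStringSet(library$sequence)
  names(ss) <- paste0(prefix, library$name)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a long-format genotype table
#'
#' One row per individual and locus with two allele calls. Duplicate
#' (individual, locus) rows are rejected: a third allele at a locus is not a
#' valid diploid call.
#'
#' @param path CSV with columns `individual`, `population`, `group`, `sex`,
#'   `locus`, `allele1`, `allele2` (extra columns are kept).
#' @return Genotype tibble.
#' @export
read_genotypes <- function(path) {
  gt <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_genotypes(gt)
}

#' @rdname read_genotypes
#' @param genotypes Genotype tibble to validate or write.
#' @export
validate_genotypes <- function(genotypes) {
  need <- c("individual", "population", "group", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(genotypes))
  if (length(miss) > 0) {
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  dup <- which(duplicated(genotypes[c("individual", "locus")]))
  if (length(dup) > 0) {
    stop("duplicated (individual, locus) genotype rows (>2 alleles at one locus): row ",
         paste(dup, collapse = ", "))
  }
  tibble::as_tibble(genotypes)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_csv(validate_genotypes(genotypes), path)
  invisible(path)
}

#' Import a wide per-individual genotype table
#'
#' Converts a wide table (one row per individual; paired allele columns per
#' locus, e.g. `UBA.1`, `UBA.2`, `DAB.1`, `DAB.2`, `DAA.1`, `DAA.2`) into the
#' long format used throughout the package. A row carrying more than two
#' allele columns for one locus is rejected with its row number.
#'
#' @param x Wide data frame or path to a CSV file.
#' @param loci Loci to look for.
#' @return Long genotype tibble (see [read_genotypes()]).
#' @export
import_wide_genotypes <- function(x, loci = c("UBA", "DAB", "DAA")) {
  wide <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    tibble::as_tibble(x)
  }
  id_cols <- intersect(c("individual", "population", "group", "sex"), names(wide))
  if (!"individual" %in% id_cols) stop("wide table needs an 'individual' column")
  long <- purrr::map_dfr(loci, function(lc) {
    cols <- grep(paste0("^", lc, "[._]"), names(wide), value = TRUE)
    if (length(cols) == 0) return(NULL)
    if (length(cols) > 2) {
      extra <- wide[, cols]
      n_called <- rowSums(!is.na(extra) & extra != "")
      bad <- which(n_called > 2)
      if (length(bad) > 0) {
        stop("row ", paste(bad, collapse = ", "), ": more than two ", lc,
             " alleles")
      }
    }
    a <- as.character(wide[[cols[1]]])
    b <- if (length(cols) >= 2) as.character(wide[[cols[2]]]) else a
    dplyr::bind_cols(wide[id_cols],
                     tibble::tibble(locus = lc, allele1 = a, allele2 = b))
  })
  for (col in setdiff(c("population", "group", "sex"), names(long))) {
    long[[col]] <- NA_character_
  }
  validate_genotypes(long[, c("individual", "population", "group", "sex",
                              "locus", "allele1", "allele2")])
}

#' Read primer pool definitions
#'
#' @param path CSV with columns `pool`, `locus`, `forward`, `reverse`, and
#'   `lineages` (pipe-separated alpha-1 lineages served; empty for class II
#'   pools that amplify all alleles).
#' @return Primer tibble with `lineages` as a list-column.
#' @export
read_primers <- function(path) {
  pr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("pool", "locus", "forward", "reverse")
  miss <- setdiff(need, names(pr))
  if (length(miss) > 0) stop("primer table lacks column(s): ", paste(miss, collapse = ", "))
  pr$lineages <- strsplit(ifelse(is.na(pr$lineages %||% NA), "", pr$lineages), "|",
                          fixed = TRUE)
  validate_primers(tibble::as_tibble(pr))
}

validate_primers <- function(primers) {
  stopifnot(all(nchar(primers$forward) > 0), all(nchar(primers$reverse) > 0))
  dup <- primers %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(dup = anyDuplicated(.data$forward) > 0)
  if (any(dup$dup)) {
    stop("pools for one locus must have distinct forward primers")
  }
  primers
}

#' Read and write paired FASTQ files
#'
#' Thin wrappers around Biostrings FASTQ support for the paired-read tibbles
#' used by the genotyper (`individual`, `read1`, `read2`, `qual1`, `qual2`).
#' Read identifiers are `<individual>/<serial>`.
#'
#' @param reads Paired-read tibble.
#' @param path1,path2 FASTQ paths for read 1 and read 2.
#' @return `write_fastq_pairs()` returns the paths invisibly;
#'   `read_fastq_pairs()` returns a paired-read tibble.
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  ids <- paste0(reads$individual, "/", seq_len(nrow(reads)))
  w <- function(seqs, quals, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  w(reads$read1, reads$qual1, path1)
  w(reads$read2, reads$qual2, path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(path1, path2) {
  # Biostrings warns about dropping its metadata columns; nothing we keep
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  stopifnot(length(r1) == length(r2))
  tibble::tibble(
    individual = sub("/\\d+$", "", names(r1)),
    read1 = unname(as.character(r1)),
    read2 = unname(as.character(r2)),
    qual1 = unname(as.character(Biostrings::quality(r1))),
    qual2 = unname(as.character(Biostrings::quality(r2)))
  )
}
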