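# CSV dialects: UTF-8, header row, '.' decimal. Pipeline outputs carry a
# '#'-prefixed provenance line (config hash + seed) that the readers skip.

read_pipeline_csv <- function(path, col_types) {
  readr::read_csv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

write_pipeline_csv <- function(df, path, provenance = NULL) {
  if (!is.null(provenance)) {
    readr::write_lines(paste0("# ", provenance), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Read and write phenotype records
#'
#' Phenotype CSV dialect: one row per plant-day with columns `accession`,
#' `treatment`, `rep`, `plant`, `day`, `length_cm`.
#'
#' @param path File path.
#' @return [read_phenotype_csv()]: tibble of root-growth records.
#' @export
read_phenotype_csv <- function(path) {
  out <- read_pipeline_csv(path, readr::cols(
    accession = readr::col_character(), treatment = readr::col_character(),
    rep = readr::col_integer(), plant = readr::col_integer(),
    day = readr::col_double(), length_cm = readr::col_double()))
  check_cols(out, c("accession", "treatment", "rep", "plant", "day", "length_cm"),
             "phenotype CSV")
  out
}

#' @rdname read_phenotype_csv
#' @param records Root-growth records tibble.
#' @param provenance Optional provenance string written as a `#` comment.
#' @export
write_phenotype_csv <- function(records, path, provenance = NULL) {
  check_cols(records, c("accession", "treatment", "rep", "plant", "day",
                        "length_cm"), "records")
  write_pipeline_csv(records, path, provenance)
}

#' Read and write genotype tables
#'
#' Genotype CSV dialect: columns `accession`, `locus`, `allele1_bp`,
#' `allele2_bp`; both allele cells blank encodes a missing genotype.
#'
#' @param path File path.
#' @return [read_genotype_csv()]: long genotype tibble.
#' @export
read_genotype_csv <- function(path) {
  out <- read_pipeline_csv(path, readr::cols(
    accession = readr::col_character(), locus = readr::col_character(),
    allele1_bp = readr::col_integer(), allele2_bp = readr::col_integer()))
  check_cols(out, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotype CSV")
  bad <- xor(is.na(out$allele1_bp), is.na(out$allele2_bp))
  if (any(bad)) {
    stop_invalid(paste0("half-missing genotype cell(s) at data row(s): ",
                        paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  out
}

#' @rdname read_genotype_csv
#' @param genotypes Long genotype tibble.
#' @param provenance Optional provenance string written as a `#` comment.
#' @export
write_genotype_csv <- function(genotypes, path, provenance = NULL) {
  check_cols(genotypes, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotypes")
  write_pipeline_csv(genotypes, path, provenance)
}

#' Read and write membership (Q) matrices
#'
#' Q-matrix CSV dialect: `accession`, `q1` .. `qk`. On read, rows whose
#' membership sum deviates from 1 by more than `tol` trigger a validation
#' warning (they are returned unchanged).
#'
#' @param path File path.
#' @param tol Row-sum tolerance (default 1e-3).
#' @return [read_q_matrix_csv()]: tibble `accession`, `q1..qk`.
#' @export
read_q_matrix_csv <- function(path, tol = 1e-3) {
  out <- read_pipeline_csv(path, readr::cols(
    accession = readr::col_character(), .default = readr::col_double()))
  qcols <- grep("^q[0-9]+$", names(out), value = TRUE)
  if (length(qcols) == 0) stop_invalid("Q-matrix CSV has no q1..qk columns")
  s <- rowSums(out[, qcols])
  off <- abs(s - 1) > tol
  if (any(off)) {
    warn(sprintf("%d Q row(s) do not sum to 1 within %g (max deviation %.3g)",
                 sum(off), tol, max(abs(s - 1))))
  }
  out
}

#' @rdname read_q_matrix_csv
#' @param q Membership tibble.
#' @param provenance Optional provenance string written as a `#` comment.
#' @export
write_q_matrix_csv <- function(q, path, provenance = NULL) {
  check_cols(q, "accession", "q")
  write_pipeline_csv(as_tibble(q), path, provenance)
}

#' Export and re-import genotypes in STRUCTURE format
#'
#' Writes the two-rows-per-accession integer-recoded format: a header line
#' of locus names, then for each accession two whitespace-separated rows
#' (label followed by one allele code per locus), `-9` for missing. The
#' recoding map (locus, integer code, allele size) is returned and is
#' required to restore base-pair sizes on re-import.
#'
#' @param genotypes Long genotype tibble.
#' @param path File path.
#' @return [write_structure()]: the recode map tibble (`locus`, `code`,
#'   `allele_bp`), invisibly.
#' @export
write_structure <- function(genotypes, path) {
  check_cols(genotypes, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotypes")
  loci <- sort(unique(genotypes$locus))
  map <- genotypes |>
    tidyr::pivot_longer(c("allele1_bp", "allele2_bp"), values_to = "allele_bp") |>
    filter(!is.na(.data$allele_bp)) |>
    distinct(.data$locus, .data$allele_bp) |>
    arrange(.data$locus, .data$allele_bp) |>
    mutate(code = dplyr::row_number(), .by = "locus")
  coded <- genotypes |>
    left_join(rename(map, code1 = "code"),
              by = c("locus", allele1_bp = "allele_bp")) |>
    left_join(rename(map, code2 = "code"),
              by = c("locus", allele2_bp = "allele_bp")) |>
    mutate(code1 = tidyr::replace_na(.data$code1, -9L),
           code2 = tidyr::replace_na(.data$code2, -9L))
  acc <- sort(unique(coded$accession))
  c1 <- tidyr::pivot_wider(select(coded, "accession", "locus", "code1"),
                           names_from = "locus", values_from = "code1")
  c2 <- tidyr::pivot_wider(select(coded, "accession", "locus", "code2"),
                           names_from = "locus", values_from = "code2")
  lines <- c(paste(loci, collapse = " "))
  for (a in acc) {
    r1 <- unlist(c1[c1$accession == a, loci])
    r2 <- unlist(c2[c2$accession == a, loci])
    lines <- c(lines, paste(c(a, r1), collapse = " "),
               paste(c(a, r2), collapse = " "))
  }
  readr::write_lines(lines, path)
  invisible(select(map, "locus", "code", "allele_bp"))
}

#' @rdname write_structure
#' @param map Recode map returned by [write_structure()].
#' @return [read_structure()]: long genotype tibble with base-pair sizes
#'   restored through `map`.
#' @export
read_structure <- function(path, map) {
  lines <- readr::read_lines(path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) %% 2 != 0) {
    abort("STRUCTURE file must hold two rows per accession",
          class = "sorgal_parse_error")
  }
  parse_row <- function(x, line_no) {
    if (length(x) != length(loci) + 1) {
      abort(sprintf("malformed STRUCTURE row at line %d", line_no),
            class = "sorgal_parse_error")
    }
    tibble(accession = x[1], locus = loci,
           code = suppressWarnings(as.integer(x[-1])))
  }
  rows <- purrr::imap(body, function(x, i) parse_row(x, i + 1L))
  odd <- bind_rows(rows[seq(1, length(rows), by = 2)]) |> rename(code1 = "code")
  even <- bind_rows(rows[seq(2, length(rows), by = 2)]) |> rename(code2 = "code")
  out <- bind_cols(odd, select(even, "code2")) |>
    left_join(rename(map, allele1_bp = "allele_bp", code1 = "code"),
              by = c("locus", "code1")) |>
    left_join(rename(map, allele2_bp = "allele_bp", code2 = "code"),
              by = c("locus", "code2")) |>
    select("accession", "locus", "allele1_bp", "allele2_bp") |>
    arrange(.data$accession, .data$locus)
  out
}

#' Read and write backcross family tables
#'
#' Family CSV dialect: `family`, `progeny`, `marker1`, `marker2` (H =
#' heterozygous, A = homozygous recurrent), `rrg_percent`. Parents CSV:
#' `family`, `TT_mean`, `tt_mean`, `Tt_mean`.
#'
#' @param path File path.
#' @return Tibble in the corresponding dialect.
#' @export
read_family_csv <- function(path) {
  out <- read_pipeline_csv(path, readr::cols(
    family = readr::col_character(), progeny = readr::col_character(),
    marker1 = readr::col_character(), marker2 = readr::col_character(),
    rrg_percent = readr::col_double(), .default = readr::col_character()))
  check_cols(out, c("family", "progeny", "marker1", "marker2", "rrg_percent"),
             "family CSV")
  out
}

#' @rdname read_family_csv
#' @param df Tibble to write.
#' @param provenance Optional provenance string written as a `#` comment.
#' @export
write_family_csv <- function(df, path, provenance = NULL) {
  write_pipeline_csv(df, path, provenance)
}
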