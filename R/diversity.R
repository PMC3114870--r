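#' Per-locus SSR allele statistics
#'
#' Counts alleles and computes frequency vectors per locus over observed
#' (non-missing) allele copies, plus panel-wide totals and the minor-allele
#' frequency list. Loci with every cell missing are excluded with a warning.
#'
#' @param genotypes Long genotype table: data frame with columns `accession`,
#'   `locus`, `allele1_bp`, `allele2_bp` (both `NA` when the cell is
#'   missing), as produced by [simulate_panel()] or [read_genotype_csv()].
#' @param maf_threshold Frequency below which an allele is counted as rare
#'   (strict inequality; default 0.10).
#' @return A list with `per_locus` (tibble: `locus`, `n_alleles`, `pic`),
#'   `frequencies` (tibble: `locus`, `allele_bp`, `count`, `freq`),
#'   `total_alleles`, `mean_alleles_per_locus` and `n_rare_alleles` (alleles
#'   with frequency strictly below `maf_threshold`).
#' @export
allele_stats <- function(genotypes, maf_threshold = 0.10) {
  check_cols(genotypes, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotypes")
  if (dplyr::n_distinct(genotypes$locus) < 1) stop_invalid("need at least one locus")
  long <- genotypes |>
    tidyr::pivot_longer(c("allele1_bp", "allele2_bp"), values_to = "allele_bp") |>
    select("locus", "allele_bp")
  empty <- long |>
    summarise(all_missing = all(is.na(.data$allele_bp)), .by = "locus") |>
    filter(.data$all_missing)
  if (nrow(empty) > 0) {
    warn(paste0("locus/loci with all cells missing excluded: ",
                paste(empty$locus, collapse = ", ")))
  }
  freq <- long |>
    filter(!is.na(.data$allele_bp)) |>
    count(.data$locus, .data$allele_bp, name = "count") |>
    mutate(freq = .data$count / sum(.data$count), .by = "locus") |>
    arrange(.data$locus, .data$allele_bp)
  per_locus <- freq |>
    summarise(n_alleles = dplyr::n(), pic = pic(.data$freq), .by = "locus")
  list(
    per_locus = per_locus,
    frequencies = freq,
    total_alleles = sum(per_locus$n_alleles),
    mean_alleles_per_locus = mean(per_locus$n_alleles),
    n_rare_alleles = sum(freq$freq < maf_threshold),
    excluded_loci = empty$locus
  )
}

#' Polymorphism information content (gene diversity)
#'
#' `1 - sum(p_i^2)` over a locus's allele frequencies. This is the
#' squared-frequency form of PIC (identical to Nei's gene diversity /
#' expected heterozygosity); the Botstein correction term is not applied.
#'
#' @param freqs Numeric frequency vector summing to 1 (tolerance 1e-6).
#' @return Value in `[0, 1 - 1/m]` for `m` alleles.
#' @export
#' @examples
#' pic(c(0.5, 0.5))          # 0.5
#' pic(c(0.5, 0.25, 0.25))   # 0.625
pic <- function(freqs) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6) {
    stop_invalid("`freqs` must be non-negative and sum to 1 (tolerance 1e-6)")
  }
  1 - sum(freqs^2)
}

#' Proportion-of-shared-alleles kinship matrix
#'
#' For each pair of accessions, the mean over jointly non-missing loci of the
#' number of allele copies shared between the two diploid genotypes (multiset
#' intersection of the two allele pairs) divided by 2. Identical homozygous
#' genotypes give 1; genotypes sharing no allele give 0.
#'
#' @inheritParams allele_stats
#' @return A list of class `kinship_psa` with `K` (symmetric numeric matrix
#'   with accession dimnames, entries in `[0, 1]`, diagonal 1 for complete
#'   data) and `n_loci` (matrix of per-pair counts of loci used).
#' @export
kinship_psa <- function(genotypes) {
  check_cols(genotypes, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotypes")
  acc <- sort(unique(genotypes$accession))
  n <- length(acc)
  if (n < 2) stop_invalid("at least 2 accessions are required")
  loci <- sort(unique(genotypes$locus))
  a1 <- a2 <- matrix(NA_integer_, n, length(loci), dimnames = list(acc, loci))
  idx <- cbind(match(genotypes$accession, acc), match(genotypes$locus, loci))
  lo <- pmin(genotypes$allele1_bp, genotypes$allele2_bp)
  hi <- pmax(genotypes$allele1_bp, genotypes$allele2_bp)
  a1[idx] <- lo
  a2[idx] <- hi

  K <- matrix(1, n, n, dimnames = list(acc, acc))
  nl <- matrix(length(loci), n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    b1 <- a1[js, , drop = FALSE]
    b2 <- a2[js, , drop = FALSE]
    x1 <- matrix(a1[i, ], length(js), length(loci), byrow = TRUE)
    x2 <- matrix(a2[i, ], length(js), length(loci), byrow = TRUE)
    c1 <- (b1 == x1) + (b2 == x1)           # copies of accession i's allele 1 in j
    c2 <- (b1 == x2) + (b2 == x2)
    shared <- ifelse(x1 == x2, pmin(2L, c1), pmin(1L, c1) + pmin(1L, c2))
    ok <- !is.na(shared)
    used <- rowSums(ok)
    if (any(used == 0)) {
      abort(paste0("accession pair(s) share no jointly genotyped locus: ",
                   paste(paste(acc[i], acc[js][used == 0], sep = "/"),
                         collapse = ", ")),
            class = "sorgal_undefined_pair")
    }
    kij <- rowSums(shared * ok, na.rm = TRUE) / (2 * used)
    K[i, js] <- K[js, i] <- kij
    nl[i, js] <- nl[js, i] <- used
  }
  # diagonal: loci observed per accession; PSA of a genotype with itself is 1
  diag(nl) <- rowSums(!is.na(a1))
  structure(list(K = K, n_loci = nl), class = "kinship_psa")
}

#' Harmonize SSR allele sizes across laboratories
#'
#' Fragment sizes for the same allele differ systematically between
#' laboratories. Given both labs' calls on a shared set of control lines,
#' estimates a per-marker integer offset as the modal difference
#' `A - B` across control-line allele calls, applies it to all of lab B's
#' panel calls, and reports the fraction of control calls consistent with
#' the mode. Markers whose modal fraction is below `min_consistency`, or
#' where the mode is tied, are flagged as failed and left unadjusted.
#'
#' @param control_a,control_b Control-line calls from labs A and B: data
#'   frames with columns `accession`, `locus`, `allele1_bp`, `allele2_bp`;
#'   both labs must have typed the same control lines at each marker.
#' @param panel_b Lab-B panel genotypes in the same format.
#' @param min_consistency Minimum modal fraction (default 0.8).
#' @return List with `panel` (adjusted lab-B genotypes) and `offsets`
#'   (tibble: `locus`, `offset`, `consistency`, `n_calls`, `status`).
#' @export
harmonize_allele_sizes <- function(control_a, control_b, panel_b,
                                   min_consistency = 0.8) {
  cols <- c("accession", "locus", "allele1_bp", "allele2_bp")
  check_cols(control_a, cols, "control_a")
  check_cols(control_b, cols, "control_b")
  check_cols(panel_b, cols, "panel_b")

  longify <- function(df, lab) {
    df |>
      mutate(lo = pmin(.data$allele1_bp, .data$allele2_bp),
             hi = pmax(.data$allele1_bp, .data$allele2_bp)) |>
      select("accession", "locus", "lo", "hi") |>
      tidyr::pivot_longer(c("lo", "hi"), names_to = "copy",
                          values_to = paste0("bp_", lab))
  }
  joint <- inner_join(longify(control_a, "a"), longify(control_b, "b"),
                      by = c("accession", "locus", "copy")) |>
    filter(!is.na(.data$bp_a), !is.na(.data$bp_b)) |>
    mutate(diff = .data$bp_a - .data$bp_b)
  if (nrow(joint) == 0) {
    stop_invalid("control tables share no jointly typed line/marker calls")
  }

  offsets <- joint |>
    summarise(
      n_calls = dplyr::n(),
      offset = {
        tab <- sort(table(.data$diff), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_real_
        else as.numeric(names(tab)[1])
      },
      consistency = max(table(.data$diff)) / dplyr::n(),
      .by = "locus"
    ) |>
    mutate(status = ifelse(is.na(.data$offset), "failed: tied mode",
                           ifelse(.data$consistency < min_consistency,
                                  "failed: low consistency", "ok")))
  if (any(offsets$status != "ok")) {
    warn(paste0("harmonization failed for marker(s): ",
                paste(offsets$locus[offsets$status != "ok"], collapse = ", ")))
  }
  apply_tab <- offsets |>
    mutate(applied = ifelse(.data$status == "ok", .data$offset, 0)) |>
    select("locus", "applied")
  panel <- panel_b |>
    left_join(apply_tab, by = "locus") |>
    mutate(applied = tidyr::replace_na(.data$applied, 0),
           allele1_bp = .data$allele1_bp + .data$applied,
           allele2_bp = .data$allele2_bp + .data$applied) |>
    select(-"applied")
  list(panel = as_tibble(panel), offsets = offsets)
}
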