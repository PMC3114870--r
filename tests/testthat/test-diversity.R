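geno_row <- function(acc, locus, a1, a2 = a1) {
  data.frame(accession = acc, locus = locus, allele1_bp = a1, allele2_bp = a2)
}

test_that("allele statistics count observed copies per locus", {
  g <- dplyr::bind_rows(
    geno_row(c("a", "b", "c", "d"), "L1", c(100L, 100L, 102L, 104L)),
    geno_row(c("a", "b", "c", "d"), "L2", 200L)
  )
  st <- allele_stats(g)
  f1 <- st$frequencies[st$frequencies$locus == "L1", ]
  expect_equal(f1$allele_bp, c(100L, 102L, 104L))
  expect_equal(f1$freq, c(0.5, 0.25, 0.25))
  expect_equal(st$per_locus$n_alleles, c(3L, 1L))
  expect_equal(st$total_alleles, 4L)
  expect_equal(st$mean_alleles_per_locus, st$total_alleles / 2)

  # an all-missing locus is excluded with a warning, and reported
  gm <- dplyr::bind_rows(g, geno_row(c("a", "b"), "L3", NA_integer_))
  expect_warning(st2 <- allele_stats(gm), "L3")
  expect_equal(st2$excluded_loci, "L3")
  expect_equal(st2$per_locus$locus, c("L1", "L2"))
})

rdirichlet_test <- function(m) {
  x <- rgamma(m, 1)
  x / sum(x)
}

test_that("PIC is gene diversity with its exact small cases and maximum", {
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.25, 0.25)), 0.625)
  for (m in 2:10) {
    expect_equal(pic(rep(1 / m, m)), 1 - 1 / m)
    # uniform frequencies maximise PIC for m alleles
    p <- as.numeric(rdirichlet_test(m))
    expect_lte(pic(p), 1 - 1 / m + 1e-12)
  }
  expect_error(pic(c(0.5, 0.6)), class = "sorgal_invalid_argument")
})

test_that("shared-allele kinship has its exact pairwise values and matrix properties", {
  g <- dplyr::bind_rows(
    geno_row("a", "L1", 100L), geno_row("b", "L1", 100L),
    geno_row("c", "L1", 102L),
    geno_row("d", "L1", 100L, 104L)
  )
  K <- kinship_psa(g)$K
  expect_equal(K["a", "b"], 1)            # identical homozygotes
  expect_equal(K["a", "c"], 0)            # no allele shared
  expect_equal(K["a", "d"], 0.5)          # A/A vs A/B: one copy of two

  set.seed(5)
  fs <- simulate_subpop_frequencies(
    2, data.frame(locus = sprintf("L%d", 1:6), n_alleles = rep(5L, 6)),
    F = 0.3, seed = 6)
  pan <- simulate_panel(fs, c(8, 8), seed = 7)
  kk <- kinship_psa(pan$genotypes)
  expect_equal(kk$K, t(kk$K))
  expect_true(all(diag(kk$K) == 1))
  expect_true(all(kk$K >= 0 & kk$K <= 1))

  # heterozygote handling through multiset intersection
  g2 <- dplyr::bind_rows(geno_row("x", "L1", 100L, 102L),
                         geno_row("y", "L1", 100L, 102L),
                         geno_row("z", "L1", 102L, 104L))
  K2 <- kinship_psa(g2)$K
  expect_equal(K2["x", "y"], 1)
  expect_equal(K2["x", "z"], 0.5)

  # a pair with no jointly observed locus is an error, not an imputation
  g3 <- dplyr::bind_rows(geno_row("p", "L1", 100L), geno_row("q", "L1", NA_integer_),
                         geno_row("p", "L2", NA_integer_), geno_row("q", "L2", 104L))
  expect_error(kinship_psa(g3), class = "sorgal_undefined_pair")
})

test_that("allele-size harmonization uses modal offsets and flags failures", {
  ctrl_a <- dplyr::bind_rows(
    geno_row(c("c1", "c2", "c3"), "L1", c(100L, 104L, 108L)),
    geno_row(c("c1", "c2", "c3"), "L2", c(200L, 202L, 204L)))
  # lab B reads L1 uniformly 2 bp small; L2 identical
  ctrl_b <- dplyr::mutate(ctrl_a,
    allele1_bp = ifelse(locus == "L1", allele1_bp - 2L, allele1_bp),
    allele2_bp = ifelse(locus == "L1", allele2_bp - 2L, allele2_bp))
  panel_b <- dplyr::bind_rows(geno_row("p1", "L1", 98L), geno_row("p1", "L2", 200L))
  h <- harmonize_allele_sizes(ctrl_a, ctrl_b, panel_b)
  expect_equal(h$offsets$offset[h$offsets$locus == "L1"], 2)
  expect_equal(h$offsets$offset[h$offsets$locus == "L2"], 0)
  expect_true(all(h$offsets$status == "ok"))
  expect_equal(h$panel$allele1_bp, c(100L, 200L))

  # idempotence: harmonizing the already-adjusted data changes nothing
  ctrl_b2 <- dplyr::mutate(ctrl_b,
    allele1_bp = ifelse(locus == "L1", allele1_bp + 2L, allele1_bp),
    allele2_bp = ifelse(locus == "L1", allele2_bp + 2L, allele2_bp))
  h2 <- harmonize_allele_sizes(ctrl_a, ctrl_b2, h$panel)
  expect_equal(h2$offsets$offset, c(0, 0))
  expect_equal(h2$panel, h$panel)

  # differences {+2, +2, -1}: modal fraction 2/3 < 0.8 -> failure flagged
  ctrl_b3 <- ctrl_a
  ctrl_b3$allele1_bp <- ctrl_a$allele1_bp - c(2L, 2L, -1L, 0L, 0L, 0L)
  ctrl_b3$allele2_bp <- ctrl_b3$allele1_bp
  expect_warning(h3 <- harmonize_allele_sizes(ctrl_a, ctrl_b3, panel_b), "L1")
  expect_match(h3$offsets$status[h3$offsets$locus == "L1"], "low consistency")
  # failed marker is left unadjusted
  expect_equal(h3$panel$allele1_bp[h3$panel$locus == "L1"], 98L)
})
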