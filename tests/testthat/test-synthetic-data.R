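loci2 <- data.frame(locus = c("L1", "L2"), n_alleles = c(4L, 6L))

test_that("subpopulation frequency draws conserve mass and share alphabets", {
  fs <- simulate_subpop_frequencies(3, loci2, F = 0.3, seed = 11)
  sums <- fs$freq |>
    dplyr::summarise(dplyr::across(c("ancestral", "pop1", "pop2", "pop3"), sum),
                     .by = "locus")
  for (cl in c("ancestral", "pop1", "pop2", "pop3")) {
    expect_true(all(abs(sums[[cl]] - 1) < 1e-9))
  }
  # same allele-size alphabet for every subpopulation, by construction
  expect_equal(dplyr::count(fs$freq, locus)$n, c(4L, 6L))
  # degenerate one-allele locus is exactly fixed everywhere
  fs1 <- simulate_subpop_frequencies(
    2, data.frame(locus = "M", n_alleles = 1L), F = 0.5, seed = 2)
  expect_equal(fs1$freq$pop1, 1)
  expect_equal(fs1$freq$pop2, 1)
  # k = 1 is allowed
  expect_equal(simulate_subpop_frequencies(1, loci2, 0.2, seed = 3)$k, 1L)
  expect_error(simulate_subpop_frequencies(0, loci2, 0.3), class = "sorgal_invalid_argument")
  expect_error(simulate_subpop_frequencies(2, loci2, 0), class = "sorgal_invalid_argument")
  expect_error(simulate_subpop_frequencies(2, loci2, 1), class = "sorgal_invalid_argument")
  # reproducible given the seed
  expect_identical(simulate_subpop_frequencies(3, loci2, 0.3, seed = 11), fs)
})

test_that("across-subpopulation frequency variance follows F * p * (1 - p)", {
  # many subpopulations around one ancestral vector act as replicate draws
  F <- 0.3
  fs <- simulate_subpop_frequencies(
    8000, data.frame(locus = "B", n_alleles = 2L), F = F, seed = 5)
  p_anc <- fs$freq$ancestral[1]
  draws <- as.numeric(fs$freq[1, paste0("pop", 1:8000)])
  expect_lt(abs(var(draws) - F * p_anc * (1 - p_anc)),
            0.1 * F * p_anc * (1 - p_anc))
})

test_that("panel simulation honours membership, selfing and the tolerance locus", {
  fs <- simulate_subpop_frequencies(3, loci2, F = 0.3, seed = 7)
  pan <- simulate_panel(fs, c(10, 10, 10), admixture_concentration = 1e-9,
                        tolerance_locus_freqs = c(1, 0, 0), seed = 8)
  q <- as.matrix(pan$q_true[, c("q1", "q2", "q3")])
  expect_true(all(abs(rowSums(q) - 1) < 1e-9))
  expect_true(all(apply(q, 1, max) > 0.999))          # concentration -> 0: one-hot
  # selfing: zero observed heterozygosity
  expect_true(all(pan$genotypes$allele1_bp == pan$genotypes$allele2_bp))
  # tolerance genotype follows the membership-weighted tolerant frequency
  tol <- dplyr::inner_join(pan$tolerance_genotype, pan$q_true, by = "accession")
  expect_true(all(tol$genotype[tol$subpop == 1] == "TT"))
  expect_true(all(tol$genotype[tol$subpop != 1] == "tt"))
  expect_error(simulate_panel(fs, c(10, 10)), class = "sorgal_invalid_argument")
  expect_error(simulate_panel(fs, c(5, 5, 5), tolerance_locus_freqs = c(2, 0, 0)),
               class = "sorgal_invalid_argument")
})

test_that("root-growth trajectories are monotone pre-noise and reproduce the indices", {
  fs <- simulate_subpop_frequencies(1, loci2, F = 0.2, seed = 1)
  pan <- simulate_panel(fs, 6, tolerance_locus_freqs = 0.5, seed = 2)
  gp0 <- default_growth_params()
  gp0$noise_sd <- 0
  gp0$rate_sd <- 0      # noiseless: no measurement error, no rate spread

  rec <- simulate_root_growth(pan, gp0, seed = 3)
  ordered <- rec |>
    dplyr::arrange(accession, treatment, rep, plant, day) |>
    dplyr::mutate(dl = length_cm - dplyr::lag(length_cm),
                  .by = c(accession, treatment, rep, plant))
  expect_true(all(ordered$dl[!is.na(ordered$dl)] >= 0))

  # no Al effect: RNRG = 100 at both days, IRG = 1
  gp1 <- gp0; gp1$m1 <- c(TT = 1, tt = 1); gp1$m2 <- c(TT = 1, tt = 1)
  prof <- tolerance_profiles(simulate_root_growth(pan, gp1, seed = 4))
  expect_equal(prof$rnrg3d, rep(100, nrow(prof)), tolerance = 1e-9)
  expect_equal(prof$rnrg5d, rep(100, nrow(prof)), tolerance = 1e-9)
  expect_equal(prof$irg, rep(1, nrow(prof)), tolerance = 1e-9)

  # complete inhibition: RNRG = 0
  gp2 <- gp0; gp2$m1 <- c(TT = 0, tt = 0); gp2$m2 <- c(TT = 0, tt = 0)
  rec2 <- simulate_root_growth(pan, gp2, seed = 5)
  expect_equal(compute_rnrg(rec2, 5)$rnrg, rep(0, 6), tolerance = 1e-9)

  # m1 = 0.4, m2 = 0.8: IRG = 2 exactly
  gp3 <- gp0; gp3$m1 <- c(TT = 0.4, tt = 0.4); gp3$m2 <- c(TT = 0.8, tt = 0.8)
  expect_equal(compute_irg(simulate_root_growth(pan, gp3, seed = 6))$irg,
               rep(2, 6), tolerance = 1e-9)

  # noiseless classification recovers the generating genotypes exactly
  prof0 <- tolerance_profiles(simulate_root_growth(pan, gp0, seed = 7)) |>
    dplyr::inner_join(pan$tolerance_genotype, by = "accession")
  expect_true(all(prof0$class[prof0$genotype == "TT"] == "tolerant"))
  expect_true(all(prof0$class[prof0$genotype == "tt"] == "sensitive"))

  expect_error(simulate_root_growth(pan, list(noise_sd = -1)),
               class = "sorgal_invalid_argument")
})

test_that("backcross families segregate 1:1 and recombine at the Haldane rate", {
  big <- simulate_bc1_family(90, 10, -0.5, 10000, marker_map = c(10, 0.2),
                             sigma = 5, seed = 9)
  n_het <- sum(big$progeny$genotype == "Tt")
  expect_gt(binom.test(n_het, 10000, 0.5)$p.value, 1e-3)
  # recombinant fraction vs marker 1 converges to haldane(10 cM)
  rec_frac <- mean((big$progeny$genotype == "Tt") != (big$progeny$marker1 == "H"))
  r <- haldane(10)
  expect_lt(abs(rec_frac - r), 3 * sqrt(r * (1 - r) / 10000))

  # complete linkage: markers identical to the locus genotype
  tight <- simulate_bc1_family(90, 10, 0, 500, marker_map = c(0, 0), seed = 10)
  expect_true(all((tight$progeny$genotype == "Tt") == (tight$progeny$marker1 == "H")))
  expect_true(all((tight$progeny$genotype == "Tt") == (tight$progeny$marker2 == "H")))

  # full dominance: F1 mean equals the tolerant-parent mean (pre-noise)
  dom <- simulate_bc1_family(90, 10, 1, 10, seed = 11)
  expect_equal(dom$parents$Tt_mean, 90)

  # moderate family size lands in the central binomial range
  fam <- simulate_bc1_family(80, 20, 0.5, 200, seed = 12)
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_true(dplyr::between(sum(fam$progeny$genotype == "Tt"), ci[1], ci[2]))

  expect_error(simulate_bc1_family(10, 90, 0, 100), class = "sorgal_invalid_argument")
})
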