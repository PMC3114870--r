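test_that("RNRG is the ratio of mean net growths, in percent", {
  # control net 5 cm, Al net 2.5 cm -> 50%
  rec <- make_records(ilc = 4, ctrl_rate = 1, al_rates13 = 0.5, al_rates35 = 0.5)
  expect_equal(compute_rnrg(rec, 5)$rnrg, 50)
  # equal growth -> 100%; arrested -> 0%
  expect_equal(compute_rnrg(make_records(4, 1, 1, 1), 5)$rnrg, 100)
  expect_equal(compute_rnrg(make_records(4, 1, 0, 0), 3)$rnrg, 0)
  # unit change and plant relabelling leave RNRG unchanged
  rec_in <- dplyr::mutate(rec, length_cm = length_cm * 2.54)
  expect_equal(compute_rnrg(rec_in, 5)$rnrg, 50)
  rec_perm <- dplyr::mutate(rec, plant = ifelse(plant == 1L, 2L, 1L))
  expect_equal(compute_rnrg(rec_perm, 5)$rnrg, 50)
  # zero control net growth is a degenerate denominator
  expect_error(compute_rnrg(make_records(4, 0, 0.5, 0.5), 5),
               class = "sorgal_degenerate_denominator")
})

test_that("IRG is the day-3-to-5 over day-1-to-3 rate ratio", {
  # lengths 5, 7, 11 at days 1, 3, 5 -> ((11-7)/2) / ((7-5)/2) = 2
  rec <- make_records(ilc = 4, ctrl_rate = 1, al_rates13 = 1, al_rates35 = 2)
  expect_equal(compute_irg(rec)$irg, 2)
  expect_equal(compute_irg(make_records(4, 1, 0.7, 0.7))$irg, 1)
  # shifting all lengths by a constant leaves IRG unchanged
  expect_equal(compute_irg(dplyr::mutate(rec, length_cm = length_cm + 10))$irg, 2)
  expect_error(compute_irg(make_records(4, 1, 0, 1)),
               class = "sorgal_degenerate_denominator")
})

test_that("RRG compares Al-phase growth to projected control growth", {
  df <- data.frame(plant = 1:3, ilc = c(4, 4, 4), flc = c(5, 5, 5),
                   flAl = c(7.5, 10, 5))
  out <- compute_rrg(df)
  expect_equal(out$rrg_percent, c(50, 100, 0))
  expect_error(compute_rrg(data.frame(ilc = 4, flc = 4, flAl = 6)),
               class = "sorgal_degenerate_denominator")
})

test_that("tolerance classes use strict 30/80 cut-offs with boundaries intermediate", {
  expect_equal(
    as.character(classify_tolerance(c(25, 29.999, 30, 55, 80, 80.001, 85))),
    c("sensitive", "sensitive", "intermediate", "intermediate",
      "intermediate", "tolerant", "tolerant"))
  expect_error(classify_tolerance(c(50, NA)), class = "sorgal_invalid_argument")
})

test_that("VRD scores aggregate to per-accession means and are range-checked", {
  sc <- data.frame(accession = rep(c("a", "b"), each = 3),
                   score = c(5L, 5L, 5L, 1L, 2L, 4L))
  out <- aggregate_vrd(sc)
  expect_equal(out$vrd, c(5, 7 / 3))
  expect_error(aggregate_vrd(data.frame(accession = "a", score = 0L)),
               class = "sorgal_invalid_argument")
  expect_error(aggregate_vrd(data.frame(accession = "a", score = 2.5)),
               class = "sorgal_invalid_argument")
})

test_that("Scott-Knott handles degenerate inputs and splits a clear two-cluster case", {
  same <- scott_knott(c(a = 5, b = 5, c = 5), r = 3, mse = 1, df_error = 6)
  expect_equal(attr(same, "n_clusters"), 1L)
  one <- scott_knott(c(only = 7), r = 3, mse = 1, df_error = 6)
  expect_equal(attr(one, "n_clusters"), 1L)
  two <- scott_knott(c(a = 10, b = 11, c = 50, d = 51),
                     r = 4, mse = 1, df_error = 12)
  expect_equal(attr(two, "n_clusters"), 2L)
  expect_equal(split(two$group, two$cluster),
               list(`1` = c("d", "c"), `2` = c("b", "a")))
  expect_equal(two$letter, c("a", "a", "b", "b"))
  expect_error(scott_knott(c(a = 1), r = 0, mse = 1, df_error = 3),
               class = "sorgal_invalid_argument")
})

test_that("Scott-Knott agrees with the exhaustive-search oracle", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    means <- rnorm(k, sd = sample(c(0.5, 2, 10), 1))
    mse <- runif(1, 0.1, 4)
    got <- scott_knott(stats::setNames(means, paste0("g", 1:k)),
                       r = 3, mse = mse, df_error = 2 * k)
    expect_equal(got$cluster, sk_oracle(means, 3, mse, 2 * k),
                 info = sprintf("replicate %d", rep))
  }
})

test_that("index PCA conserves the trace and reproduces the correlation structure", {
  set.seed(17)
  n <- 4000
  iso <- tibble::tibble(accession = as.character(1:n),
                        rnrg3d = rnorm(n), rnrg5d = rnorm(n), irg = rnorm(n))
  p <- pca_indices(iso)
  expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-8)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
  expect_true(all(abs(p$proportion - 1 / 3) < 0.05))   # isotropy at large n

  col <- tibble::tibble(accession = as.character(1:50), rnrg3d = 1:50,
                        rnrg5d = 2 * (1:50) + 3, irg = -(1:50))
  expect_equal(pca_indices(col)$proportion[1], 1, tolerance = 1e-12)

  # scores' covariance is diag(eigenvalues)
  mix <- tibble::tibble(accession = as.character(1:500),
                        rnrg3d = rnorm(500))
  mix$rnrg5d <- mix$rnrg3d * 0.8 + rnorm(500, sd = 0.5)
  mix$irg <- rnorm(500)
  pm <- pca_indices(mix)
  cv <- cov(as.matrix(pm$scores[, c("PC1", "PC2", "PC3")]))
  expect_equal(cv, diag(pm$eigenvalues), tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention: dominant loading positive
  expect_true(all(apply(pm$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

  flat <- dplyr::mutate(mix, irg = 1)
  expect_error(pca_indices(flat), class = "sorgal_invalid_argument")
})
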