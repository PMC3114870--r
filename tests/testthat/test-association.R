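test_that("chi-squared independence test matches closed forms and conserves margins", {
  perfect <- matrix(c(10, 20, 5, 10), 2)      # rows proportional to margins
  r0 <- chi_square_independence(perfect)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  r1 <- chi_square_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r1$statistic, 20)
  expect_equal(r1$df, 1)

  set.seed(9)
  tab <- matrix(rpois(12, 20) + 1, nrow = 6)  # six classes x two outcomes
  r2 <- chi_square_independence(tab)
  expect_equal(r2$df, 5)
  expect_equal(rowSums(r2$expected), rowSums(tab), tolerance = 1e-9)
  expect_equal(colSums(r2$expected), colSums(tab), tolerance = 1e-9)

  expect_error(chi_square_independence(matrix(c(1, 2, 0, 0), 2)),
               class = "sorgal_invalid_argument")
})

test_that("Kruskal-Wallis H matches rank arithmetic and is rank-invariant", {
  d <- data.frame(v = c(1, 2, 100, 200), g = c("a", "a", "b", "b"))
  kw <- kruskal_wallis(d, "v", "g")
  # ranks 1,2,3,4: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1) = 2.4
  expect_equal(kw$H, 2.4)
  expect_equal(kw$df, 1)
  # invariant under a strictly monotone transform
  d2 <- dplyr::mutate(d, v = log(v))
  expect_equal(kruskal_wallis(d2, "v", "g")$H, kw$H)
  expect_error(kruskal_wallis(data.frame(v = rep(1, 6), g = rep(c("a", "b"), 3)),
                              "v", "g"),
               class = "sorgal_degenerate_data")
  expect_error(kruskal_wallis(data.frame(v = 1:3, g = "a"), "v", "g"),
               class = "sorgal_invalid_argument")
})

test_that("non-parametric lsd reproduces its hand value and letter contracts", {
  expect_equal(lsd_value(10, 10, 20), 1.96 * sqrt(35 * 0.2), tolerance = 1e-3)
  expect_equal(lsd_value(10, 10, 20), 5.1856, tolerance = 1e-4)

  # equal mean ranks: one shared letter
  d <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  r <- nonparametric_lsd(d, "v", "g")
  expect_true(all(r$groups$letters == "a"))
  expect_true(all(!r$pairs$significant))

  # non-transitive pattern: extremes differ, middle group overlaps both
  set.seed(12)
  d2 <- data.frame(
    v = c(rnorm(12, 0, 0.2), rnorm(12, 1.2, 0.2), rnorm(12, 2.4, 0.2)),
    g = rep(c("lo", "mid", "hi"), each = 12))
  r2 <- nonparametric_lsd(d2, "v", "g")
  gl <- stats::setNames(r2$groups$letters, r2$groups$group)
  shared <- function(i, j) {
    any(strsplit(gl[[i]], "")[[1]] %in% strsplit(gl[[j]], "")[[1]])
  }
  # letters must encode exactly the pairwise decisions
  for (p in seq_len(nrow(r2$pairs))) {
    expect_equal(!shared(r2$pairs$group_i[p], r2$pairs$group_j[p]),
                 r2$pairs$significant[p])
  }
  expect_error(nonparametric_lsd(d, "v", "g", alpha = 1.5),
               class = "sorgal_invalid_argument")
})

test_that("Q+K collapses to ordinary least squares when kinship is uninformative", {
  set.seed(33)
  n <- 40
  acc <- sprintf("a%02d", 1:n)
  # identity kinship: 2K vg + I vr is isotropic, so the fit is exactly OLS
  K <- diag(n); dimnames(K) <- list(acc, acc)
  q <- tibble::tibble(accession = acc, q1 = runif(n))
  y <- 2 + 3 * q$q1 + rnorm(n)
  pheno <- tibble::tibble(accession = acc, value = y, n_obs = 1)
  fit <- fit_qk(pheno, q, K)
  ols <- stats::lm(y ~ q$q1)
  expect_equal(fit$lnl_ml, as.numeric(stats::logLik(ols)), tolerance = 1e-6)
  expect_equal(fit$fixef$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("Q+K ML and REML match the brute-force multivariate-normal oracle", {
  set.seed(34)
  n <- 15
  acc <- sprintf("a%02d", 1:n)
  M <- matrix(rnorm(n * 30), n)
  K <- stats::cov2cor(tcrossprod(M))
  dimnames(K) <- list(acc, acc)
  n_obs <- sample(1:4, n, replace = TRUE)
  q <- tibble::tibble(accession = acc, q1 = runif(n))
  Sig <- 2 * K * 1.5 + diag(1 / n_obs) * 1
  y <- as.numeric(1 + 2 * q$q1 + t(chol(Sig)) %*% rnorm(n))
  pheno <- tibble::tibble(accession = acc, value = y, n_obs = n_obs)
  fit <- fit_qk(pheno, q, K)
  lnl_oracle <- qk_oracle_ml(y, cbind(1, q$q1), K, n_obs)
  expect_lt(abs(fit$lnl_ml - lnl_oracle), 1e-4)
  expect_true(fit$vg >= 0 && fit$vr >= 0)
  expect_equal(fit$p, 4)

  # log-likelihood is invariant to a consistent reordering of accessions
  ord <- sample(n)
  fit2 <- fit_qk(pheno[ord, ], q[ord, ], K)
  expect_equal(fit2$lnl_ml, fit$lnl_ml, tolerance = 1e-6)
  expect_equal(fit2$lnl_reml, fit$lnl_reml, tolerance = 1e-6)

  expect_error(fit_qk(pheno, dplyr::mutate(q, q2 = q1), K),
               class = "sorgal_rank_deficiency")
  Kbad <- K; Kbad[1, 2] <- Kbad[2, 1] <- 50
  expect_error(fit_qk(pheno, q, Kbad), class = "sorgal_invalid_argument")
})

test_that("variance-ratio estimation recovers Vg/Vr = 2 in repeated draws", {
  set.seed(35)
  n <- 120
  acc <- sprintf("a%03d", 1:n)
  M <- matrix(rnorm(n * 60), n)
  K <- stats::cov2cor(tcrossprod(M) + diag(n) * 1e-8)
  dimnames(K) <- list(acc, acc)
  ch <- chol(2 * K * 2 + diag(n) * 1)     # Vg = 2, Vr = 1
  pheno <- tibble::tibble(accession = acc, value = 0, n_obs = 1)
  ratios <- vapply(1:60, function(i) {
    pheno$value <- as.numeric(10 + t(ch) %*% rnorm(n))
    fit_qk(pheno, NULL, K)$ratio
  }, numeric(1))
  expect_true(median(ratios) > 1.6 && median(ratios) < 2.4)
})

test_that("BIC sequential exclusion ranks subpopulation contributions", {
  set.seed(36)
  n <- 120
  acc <- sprintf("a%03d", 1:n)
  qm <- matrix(rgamma(n * 4, 0.3), n)
  qm <- qm / rowSums(qm)
  colnames(qm) <- paste0("q", 1:4)
  q <- dplyr::bind_cols(tibble::tibble(accession = acc), tibble::as_tibble(qm))
  K <- diag(n); dimnames(K) <- list(acc, acc)

  # strong effect on q2, weaker on q1/q3; q4 is the dependency drop
  y <- 10 + 4 * qm[, 1] + 20 * qm[, 2] + 4 * qm[, 3] + rnorm(n, sd = 2)
  pheno <- tibble::tibble(accession = acc, value = y, n_obs = 1)
  tab <- sequential_exclusion(pheno, q, K, drop_dependency = "q4")
  expect_equal(tab$model[1], "complete")
  expect_equal(nrow(tab), 4)
  worst <- tab$excluded[which.max(tab$delta_bic)]
  expect_equal(worst, "q2")
  expect_error(sequential_exclusion(pheno, q, K, drop_dependency = "q9"),
               class = "sorgal_invalid_argument")
})

test_that("structure R-squared has its exact limits and recovers a known share", {
  set.seed(37)
  n <- 250
  acc <- sprintf("a%03d", 1:n)
  qm <- matrix(rgamma(n * 3, 0.4), n)
  qm <- qm / rowSums(qm)
  q <- tibble::tibble(accession = acc, q1 = qm[, 1], q2 = qm[, 2])

  y_exact <- 3 * qm[, 1] - 2 * qm[, 2] + 1
  expect_equal(structure_r2(tibble::tibble(accession = acc, value = y_exact), q), 1,
               tolerance = 1e-12)

  resid <- residuals(stats::lm(rnorm(n) ~ qm[, 1] + qm[, 2]))
  expect_equal(structure_r2(tibble::tibble(accession = acc, value = resid + 5), q),
               0, tolerance = 1e-12)

  # signal:noise 1:4 by construction -> R^2 near 0.2
  sig <- scale(3 * qm[, 1] - 2 * qm[, 2])[, 1]
  y <- sig + rnorm(n, sd = 2)
  r2 <- structure_r2(tibble::tibble(accession = acc, value = y), q)
  expect_lt(abs(r2 - 0.2), 0.05)

  qq <- dplyr::mutate(q, q3 = 1 - q1 - q2)
  expect_error(structure_r2(tibble::tibble(accession = acc, value = y), qq),
               class = "sorgal_rank_deficiency")
})
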