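#' Pearson chi-squared test of independence
#'
#' Classical contingency-table test with expected counts from the row and
#' column margins, no continuity correction, and the p-value from the
#' chi-squared distribution at `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param tab Matrix (or table) of non-negative counts; every row and
#'   column must have a positive sum.
#' @return An object of class `contingency_result`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(10, 0, 0, 10), 2))  # chi2 = 20, df = 1
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop_invalid("all counts must be finite and non-negative")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_invalid("every row and column must have a positive sum")
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(observed = tab, expected = fit$expected,
         statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = unname(fit$p.value)),
    class = "contingency_result"
  )
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with mid-ranks and a chi-squared p-value
#' at `groups - 1` degrees of freedom; used for the subpopulation
#' comparisons where group sizes and variances are unequal.
#'
#' @param data Data frame containing the value and group columns.
#' @param value,group Column names (unquoted) of the response and grouping
#'   variable.
#' @return Tibble with one row: `H`, `df`, `p_value`, `n_groups`, `N`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stop_invalid("at least 2 non-empty groups are required")
  }
  if (length(unique(v)) == 1) {
    abort("all values identical: H undefined after tie correction",
          class = "sorgal_degenerate_data")
  }
  fit <- stats::kruskal.test(v, g)
  tibble(H = unname(fit$statistic), df = unname(fit$parameter),
         p_value = unname(fit$p.value), n_groups = nlevels(g), N = length(v))
}

#' Non-parametric least-significant-difference value
#'
#' Dunn-style critical difference between mean ranks of two groups:
#' `z[1 - alpha/2] * sqrt(N * (N + 1) / 12 * (1/n_i + 1/n_j))`.
#'
#' @param n_i,n_j Group sizes.
#' @param N Total number of observations ranked.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The least significant difference on the mean-rank scale.
#' @export
#' @examples
#' lsd_value(10, 10, 20)   # 1.96 * sqrt(35 * 0.2) = 5.186
lsd_value <- function(n_i, n_j, N, alpha = 0.05) {
  if (any(c(n_i, n_j) < 1)) stop_invalid("group sizes must be positive")
  alpha <- check_prob_open(alpha, "alpha")
  stats::qnorm(1 - alpha / 2) * sqrt(N * (N + 1) / 12 * (1 / n_i + 1 / n_j))
}

#' Non-parametric lsd comparison of groups with letter codes
#'
#' Assigns mid-ranks over the pooled sample, compares every pair of groups
#' by the Dunn-style least significant difference on mean ranks
#' ([lsd_value()]) with no multiplicity adjustment, and encodes the pairwise
#' decisions as letters by the insert-and-absorb procedure over groups
#' sorted by decreasing mean rank (groups sharing a letter do not differ).
#' The overall Kruskal-Wallis test is reported alongside.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Pairwise significance level (default 0.05).
#' @return An object of class `rank_comparison`: list with `groups` (tibble:
#'   `group`, `n`, `mean_rank`, `letters`), `pairs` (tibble: `group_i`,
#'   `group_j`, `diff`, `lsd`, `significant`), `kruskal` (tibble from
#'   [kruskal_wallis()]), `N` and `alpha`.
#' @export
nonparametric_lsd <- function(data, value, group, alpha = 0.05) {
  alpha <- check_prob_open(alpha, "alpha")
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (any(table(g) == 0)) stop_invalid("every group must be non-empty")
  N <- length(v)
  rk <- rank(v)                    # mid-ranks
  groups <- tibble(group = levels(g),
                   n = as.integer(table(g)),
                   mean_rank = as.numeric(tapply(rk, g, mean))) |>
    arrange(desc(.data$mean_rank))

  pairs <- tidyr::expand_grid(i = seq_len(nrow(groups)), j = seq_len(nrow(groups))) |>
    filter(.data$i < .data$j) |>
    mutate(
      group_i = groups$group[.data$i], group_j = groups$group[.data$j],
      diff = abs(groups$mean_rank[.data$i] - groups$mean_rank[.data$j]),
      lsd = lsd_value(groups$n[.data$i], groups$n[.data$j], N, alpha),
      significant = .data$diff > .data$lsd
    ) |>
    select("group_i", "group_j", "diff", "lsd", "significant")

  groups$letters <- assign_letters(nrow(groups),
                                   cbind(pairs_idx(groups, pairs)))
  structure(
    list(groups = groups, pairs = pairs,
         kruskal = kruskal_wallis(data, {{ value }}, {{ group }}),
         N = N, alpha = alpha),
    class = "rank_comparison"
  )
}

pairs_idx <- function(groups, pairs) {
  sig <- pairs[pairs$significant, , drop = FALSE]
  cbind(match(sig$group_i, groups$group), match(sig$group_j, groups$group))
}

# insert-and-absorb letter assignment: groups are indexed 1..k in display
# order; `sig` is a 2-column matrix of significantly different pairs
assign_letters <- function(k, sig) {
  cols <- list(seq_len(k))
  if (nrow(sig) > 0) {
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1]; j <- sig[r, 2]
      new_cols <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          new_cols <- c(new_cols, list(cl))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cl) i %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Fit the Q+K unified mixed model
#'
#' Fits `y = Q nu + Z u + e` for one trait: fixed effects are an intercept
#' plus the included population-membership columns; the random accession
#' effect has covariance `2 K Vg` with `K` the proportion-of-shared-alleles
#' kinship matrix; the residual covariance is `R V_R` with
#' `R = diag(1 / n_obs)` (each phenotype is a mean of `n_obs` plants).
#' Variance components are estimated by a one-dimensional profile
#' likelihood over the ratio `Vg / V_R` after simultaneous diagonalization
#' (log-spaced grid followed by golden-section/parabolic refinement,
#' relative tolerance 1e-8 in the ratio), constrained non-negative. Both ML
#' and REML log-likelihoods are reported; `BIC = -2 lnL_ML + p log(n)` with
#' `p = #fixed effects + 2`, computed from the ML likelihood because models
#' compared by [sequential_exclusion()] differ in their fixed effects.
#'
#' @param pheno Data frame with columns `accession`, the trait column and
#'   `n_obs` (observations behind each phenotypic mean; defaults to 1 when
#'   absent).
#' @param q Membership tibble (`accession`, membership columns) whose
#'   non-accession columns enter as fixed effects; pass the already-reduced
#'   set of columns (one dropped for dependency). `NULL` fits an
#'   intercept-only fixed part.
#' @param kinship A [kinship_psa()] result or a symmetric PSD matrix with
#'   accession dimnames.
#' @param trait Trait column name (default `"value"`).
#' @return An object of class `qk_fit`: list with `fixef` (tibble), `vg`,
#'   `vr`, `ratio`, `lnl_ml`, `lnl_reml`, `bic`, `p` (BIC parameter count),
#'   `n` and `included` (fixed-effect labels).
#' @export
fit_qk <- function(pheno, q = NULL, kinship, trait = "value") {
  check_cols(pheno, c("accession", trait), "pheno")
  K <- if (inherits(kinship, "kinship_psa")) kinship$K else as.matrix(kinship)
  acc <- pheno$accession
  if (is.null(rownames(K)) || !all(acc %in% rownames(K))) {
    stop_invalid("`kinship` must carry accession dimnames covering the phenotypes")
  }
  K <- K[acc, acc]
  if (max(abs(K - t(K))) > 1e-8) stop_invalid("`kinship` must be symmetric")
  y <- pheno[[trait]]
  n <- length(y)
  n_obs <- if ("n_obs" %in% names(pheno)) pheno$n_obs else rep(1, n)
  if (any(n_obs < 1)) stop_invalid("`n_obs` must be >= 1")

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(q)) {
    qdf <- as.data.frame(q)
    qcols <- setdiff(names(qdf), c("accession", "subpop"))
    qm <- as.matrix(qdf[match(acc, qdf$accession), qcols, drop = FALSE])
    X <- cbind(X, qm)
  }
  if (qr(X)$rank < ncol(X)) {
    abort("fixed-effect design is rank deficient (collinear Q columns)",
          class = "sorgal_rank_deficiency")
  }
  px <- ncol(X)

  w <- sqrt(n_obs)
  A <- 2 * (w * K) %*% diag(w, n)        # 2 W K W
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values), 1)) {
    stop_invalid("`kinship` is not positive semi-definite beyond tolerance")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, w * y))
  Xs <- crossprod(U, X * w)
  log_nobs <- sum(log(n_obs))

  prof <- function(delta, reml) {
    v <- 1 + delta * d
    sv <- sqrt(v)
    Xw <- Xs / sv
    yw <- ys / sv
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    logdet <- sum(log(v)) - log_nobs
    if (reml) {
      df <- n - px
      s2 <- rss / df
      xx <- crossprod(Xw)
      as.numeric(-0.5 * (df * log(2 * pi * s2) + logdet +
                           determinant(xx, logarithm = TRUE)$modulus + df))
    } else {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi * s2) + logdet + n)
    }
  }
  profile_max <- function(reml) {
    grid <- c(0, 10^seq(-6, 6, length.out = 61))
    ll <- vapply(grid, prof, numeric(1), reml = reml)
    i <- which.max(ll)
    if (i == 1) {
      opt <- stats::optimize(prof, c(0, grid[2]), reml = reml,
                             maximum = TRUE, tol = 1e-10)
    } else {
      lo <- grid[max(1, i - 1)]
      hi <- grid[min(length(grid), i + 1)]
      opt <- stats::optimize(function(ld) prof(exp(ld), reml),
                             log(c(max(lo, 1e-12), hi)),
                             maximum = TRUE, tol = 1e-8)
      opt <- list(maximum = exp(opt$maximum), objective = opt$objective)
    }
    if (ll[1] >= opt$objective) list(delta = 0, lnl = ll[1])
    else list(delta = opt$maximum, lnl = opt$objective)
  }

  ml <- profile_max(reml = FALSE)
  reml <- profile_max(reml = TRUE)

  # components and fixed effects at the ML optimum
  v <- 1 + ml$delta * d
  sv <- sqrt(v)
  fit <- stats::lm.fit(Xs / sv, ys / sv)
  vr <- sum(fit$residuals^2) / n
  vg <- ml$delta * vr
  # REML-scale components at the REML optimum
  v_r <- 1 + reml$delta * d
  fit_r <- stats::lm.fit(Xs / sqrt(v_r), ys / sqrt(v_r))
  vr_reml <- sum(fit_r$residuals^2) / (n - px)
  vg_reml <- reml$delta * vr_reml

  p_bic <- px + 2
  structure(
    list(
      fixef = tibble(term = colnames(X), estimate = unname(fit$coefficients)),
      vg = vg, vr = vr, ratio = ml$delta,
      vg_reml = vg_reml, vr_reml = vr_reml, ratio_reml = reml$delta,
      lnl_ml = ml$lnl, lnl_reml = reml$lnl,
      bic = -2 * ml$lnl + p_bic * log(n),
      p = p_bic, n = n, trait = trait,
      included = setdiff(colnames(X), "(Intercept)")
    ),
    class = "qk_fit"
  )
}

#' Sequential subpopulation exclusion by BIC
#'
#' Fits the complete Q+K model (intercept plus all membership columns except
#' the designated dependency drop) and every reduced model obtained by
#' removing one further subpopulation column, and ranks the resulting BIC
#' increases. A subpopulation whose removal raises BIC most captures the
#' largest share of the trait variation.
#'
#' @inheritParams fit_qk
#' @param q Full membership tibble (`accession`, `q1..qk`).
#' @param drop_dependency Label of the column dropped from all models to
#'   remove the rows-sum-to-one dependency. Default: the column with the
#'   lowest phenotypic variance contribution (smallest single-column OLS
#'   R-squared against the trait).
#' @return An object of class `qk_model_table`: tibble with `model`,
#'   `excluded`, `lnl_ml`, `lnl_reml`, `vg`, `vr`, `p`, `bic`, `delta_bic`
#'   (BIC minus the complete model's), sorted with the complete model
#'   first; attribute `drop_dependency`.
#' @export
sequential_exclusion <- function(pheno, q, kinship, trait = "value",
                                 drop_dependency = NULL) {
  qdf <- as.data.frame(q)
  qcols <- setdiff(names(qdf), c("accession", "subpop"))
  if (length(qcols) < 2) stop_invalid("`q` must contain at least 2 membership columns")
  if (is.null(drop_dependency)) {
    y <- pheno[[trait]][match(qdf$accession, pheno$accession)]
    r2 <- vapply(qcols, function(cl) {
      summary(stats::lm(y ~ qdf[[cl]]))$r.squared
    }, numeric(1))
    drop_dependency <- qcols[which.min(r2)]
  }
  if (!drop_dependency %in% qcols) {
    stop_invalid(sprintf("dependency column `%s` is not a column of `q`",
                         drop_dependency))
  }
  included <- setdiff(qcols, drop_dependency)
  fits <- c(
    list(complete = fit_qk(pheno, qdf[, c("accession", included)], kinship, trait)),
    stats::setNames(
      lapply(included, function(cl) {
        fit_qk(pheno, qdf[, c("accession", setdiff(included, cl))], kinship, trait)
      }),
      paste0("excl_", included))
  )
  tab <- purrr::imap(fits, function(f, nm) {
    tibble(model = nm,
           excluded = if (nm == "complete") NA_character_ else sub("^excl_", "", nm),
           lnl_ml = f$lnl_ml, lnl_reml = f$lnl_reml,
           vg = f$vg, vr = f$vr, p = f$p, bic = f$bic)
  }) |> bind_rows() |>
    mutate(delta_bic = .data$bic - .data$bic[1])
  structure(tab, class = c("qk_model_table", class(tibble())),
            drop_dependency = drop_dependency, trait = trait)
}

#' Variance explained by population structure alone
#'
#' Ordinary least-squares R-squared of the trait on an intercept plus the
#' included membership columns (a deterministic surrogate for stepwise
#' maximum-R-squared selection; all included columns enter at once).
#'
#' @inheritParams fit_qk
#' @param q Membership tibble whose non-accession columns all enter the
#'   regression; pass a reduced set to avoid the rows-sum-to-one
#'   collinearity.
#' @return Scalar R-squared in `[0, 1]`.
#' @export
structure_r2 <- function(pheno, q, trait = "value") {
  check_cols(pheno, c("accession", trait), "pheno")
  qdf <- as.data.frame(q)
  qcols <- setdiff(names(qdf), c("accession", "subpop"))
  qm <- as.matrix(qdf[match(pheno$accession, qdf$accession), qcols, drop = FALSE])
  y <- pheno[[trait]]
  if (length(y) <= ncol(qm) + 1) stop_invalid("need n > #columns + 1 observations")
  X <- cbind(1, qm)
  if (qr(X)$rank < ncol(X)) {
    abort("membership design is rank deficient; drop a dependent column",
          class = "sorgal_rank_deficiency")
  }
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}
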