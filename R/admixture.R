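#' Fit a Bayesian admixture model to SSR genotypes by Gibbs sampling
#'
#' Clusters multi-allelic genotypes under the admixture model: each
#' accession has a membership vector `Q` over `k` clusters and each cluster
#' has its own allele-frequency vectors `P` (independent per-cluster
#' Dirichlet priors with parameter `lambda`; the correlated-frequencies
#' prior of the original STRUCTURE software is deliberately not used — the
#' model is labelled accordingly in the output). The Gibbs sweep samples,
#' in turn, the cluster of origin `Z` of every allele copy from the product
#' of `Q` and `P` terms, `P` from Dirichlet posteriors given the Z-assigned
#' allele counts, and `Q` from `Dirichlet(alpha + per-accession Z counts)`.
#' Reported `Q` and `P` are posterior means over post-burn-in sweeps, and
#' `Ln P(D)` is estimated as `mean(lnL) - var(lnL) / 2` over the same
#' sweeps.
#'
#' @inheritParams allele_stats
#' @param k Number of clusters (1 <= k <= number of accessions).
#' @param burnin Burn-in sweeps (default 2000).
#' @param iters Total sweeps including burn-in (default 10000).
#' @param alpha Dirichlet admixture parameter (fixed, default 1).
#' @param lambda Dirichlet prior parameter for allele frequencies
#'   (default 1).
#' @param seed Integer seed.
#' @return An object of class `structure_run`: list with `k`, `Q` (tibble
#'   `accession`, `q1..qk`, rows sum to 1), `P` (list per locus of cluster x
#'   allele frequency matrices, posterior means), `ln_pd`, `lnl_trace`
#'   (post-burn-in log-likelihood trace), `model`
#'   (`"admixture, independent allele frequencies"`) and `settings`.
#' @export
fit_admixture <- function(genotypes, k, burnin = 2000, iters = 10000,
                          alpha = 1, lambda = 1, seed = 1L) {
  check_cols(genotypes, c("accession", "locus", "allele1_bp", "allele2_bp"),
             "genotypes")
  k <- check_count(k, "k")
  burnin <- check_count(burnin, "burnin", min = 0L)
  iters <- check_count(iters, "iters")
  if (iters <= burnin) stop_invalid("`iters` must exceed `burnin`")
  if (alpha <= 0 || lambda <= 0) stop_invalid("`alpha` and `lambda` must be positive")

  acc <- sort(unique(genotypes$accession))
  n <- length(acc)
  if (k > n) stop_invalid("`k` must not exceed the number of accessions")
  loci <- sort(unique(genotypes$locus))
  L <- length(loci)

  # integer-recode alleles per locus; copies as two n x L matrices
  g <- genotypes |>
    mutate(i = match(.data$accession, acc), l = match(.data$locus, loci))
  A1 <- A2 <- matrix(NA_integer_, n, L)
  alphabet <- vector("list", L)
  for (l in seq_len(L)) {
    gl <- g[g$l == l, ]
    sizes <- sort(unique(stats::na.omit(c(gl$allele1_bp, gl$allele2_bp))))
    alphabet[[l]] <- sizes
    A1[gl$i, l] <- match(gl$allele1_bp, sizes)
    A2[gl$i, l] <- match(gl$allele2_bp, sizes)
  }
  m <- lengths(alphabet)
  obs <- lapply(seq_len(L), function(l) which(!is.na(A1[, l])))

  withr_seed(seed)
  Q <- rdirichlet(n, rep(1, k))
  P <- lapply(seq_len(L), function(l) rdirichlet(k, rep(1, m[l])))

  q_acc <- matrix(0, n, k)
  p_acc <- lapply(seq_len(L), function(l) matrix(0, k, m[l]))
  lnl_trace <- numeric(iters - burnin)
  n_post <- 0L

  for (sweep in seq_len(iters)) {
    cnt <- matrix(0, n, k)          # per-accession cluster counts
    lnl <- 0
    for (l in seq_len(L)) {
      ol <- obs[[l]]
      if (length(ol) == 0) next
      Pl <- P[[l]]
      acnt <- numeric(k * m[l])     # cluster x allele counts (column-major)
      for (a_mat in list(A1, A2)) {
        a <- a_mat[ol, l]
        w <- Q[ol, , drop = FALSE] * t(Pl[, a, drop = FALSE])
        tot <- rowSums(w)
        tot[tot == 0] <- .Machine$double.xmin
        lnl <- lnl + sum(log(tot))
        if (k == 1L) {
          z <- rep(1L, length(ol))
        } else {
          cw <- w
          for (j in 2:k) cw[, j] <- cw[, j] + cw[, j - 1]
          u <- stats::runif(length(ol)) * cw[, k]
          z <- rowSums(cw < u) + 1L
        }
        cnt[cbind(ol, z)] <- cnt[cbind(ol, z)] + 1
        acnt <- acnt + tabulate(z + k * (a - 1L), nbins = k * m[l])
      }
      # P update: Dirichlet posterior per cluster
      gam <- matrix(stats::rgamma(k * m[l], shape = lambda + acnt), k, m[l])
      P[[l]] <- gam / pmax(rowSums(gam), .Machine$double.xmin)
    }
    if (!is.finite(lnl)) {
      abort("non-finite likelihood in admixture sampler",
            class = "sorgal_numerical_failure")
    }
    # Q update
    gq <- matrix(stats::rgamma(n * k, shape = alpha + cnt), n, k)
    Q <- gq / pmax(rowSums(gq), .Machine$double.xmin)
    if (sweep > burnin) {
      n_post <- n_post + 1L
      lnl_trace[n_post] <- lnl
      q_acc <- q_acc + Q
      for (l in seq_len(L)) p_acc[[l]] <- p_acc[[l]] + P[[l]]
    }
  }

  q_mean <- q_acc / n_post
  colnames(q_mean) <- paste0("q", seq_len(k))
  p_mean <- lapply(seq_len(L), function(l) {
    pm <- p_acc[[l]] / n_post
    dimnames(pm) <- list(paste0("cluster", seq_len(k)), alphabet[[l]])
    pm
  })
  names(p_mean) <- loci
  ln_pd <- mean(lnl_trace) - stats::var(lnl_trace) / 2
  if (n_post == 1L) ln_pd <- lnl_trace

  structure(
    list(
      k = k,
      Q = bind_cols(tibble(accession = acc), as_tibble(q_mean)),
      P = p_mean,
      ln_pd = ln_pd,
      lnl_trace = lnl_trace,
      model = "admixture, independent allele frequencies",
      settings = list(burnin = burnin, iters = iters, alpha = alpha,
                      lambda = lambda, seed = as.integer(seed))
    ),
    class = "structure_run"
  )
}

#' Align cluster labels of a membership matrix to a reference
#'
#' Admixture-model clusters are identified only up to label permutation.
#' Greedily matches columns of `Q` to columns of `ref` by Pearson
#' correlation (highest correlation pairs matched first), then returns `Q`
#' with its columns reordered to the reference labels.
#'
#' @param q,ref Membership matrices or tibbles with an optional `accession`
#'   column and the same number of membership columns.
#' @return Matrix of `q`'s membership columns in reference order.
#' @export
align_q_labels <- function(q, ref) {
  qm <- q_as_matrix(q)
  rm_ <- q_as_matrix(ref)
  k <- ncol(qm)
  if (ncol(rm_) != k) stop_invalid("`q` and `ref` must have the same number of clusters")
  if (k == 1) return(qm)
  cc <- suppressWarnings(stats::cor(qm, rm_))
  cc[!is.finite(cc)] <- -Inf
  perm <- integer(k)
  for (step in seq_len(k)) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    perm[best[2]] <- best[1]
    cc[best[1], ] <- -Inf
    cc[, best[2]] <- -Inf
  }
  qm[, perm, drop = FALSE]
}

q_as_matrix <- function(q) {
  if (is.matrix(q)) return(q)
  df <- as.data.frame(q)
  df <- df[, setdiff(names(df), c("accession", "subpop")), drop = FALSE]
  as.matrix(df)
}

#' Evanno delta-k table from replicate admixture runs
#'
#' Given `Ln P(D)` estimates from independent runs at a contiguous range of
#' cluster counts, computes per-k mean and standard deviation of `Ln P(D)`,
#' the first- and second-order differences and the Evanno statistic
#' `delta_k = mean over runs of |L''(k)| / sd over runs of L(k)`, defined
#' only at interior k with positive sd. delta-k is invariant to adding a
#' constant to all `Ln P(D)` values.
#'
#' @param runs Data frame with columns `k`, `run`, `ln_pd`: one row per
#'   independent run. The k values must form a contiguous range of length
#'   >= 3 with at least 2 runs each.
#' @return An object of class `evanno_table`: tibble with columns `k`,
#'   `n_runs`, `mean_ln_pd`, `sd_ln_pd`, `l_prime` (mean L'(k)),
#'   `l_second` (mean |L''(k)|) and `delta_k` (`NA` at the endpoints; `NA`
#'   with a warning where the sd is zero).
#' @export
#' @examples
#' runs <- data.frame(
#'   k = rep(2:4, each = 2), run = rep(1:2, 3),
#'   ln_pd = c(-100, -102, -80, -82, -78, -80))
#' evanno_delta_k(runs)   # delta_k(3) = 18 / sqrt(2)
evanno_delta_k <- function(runs) {
  check_cols(runs, c("k", "run", "ln_pd"), "runs")
  ks <- sort(unique(runs$k))
  if (length(ks) < 3 || !all(diff(ks) == 1)) {
    stop_invalid("`runs` must cover a contiguous k range of length >= 3")
  }
  nr <- runs |> count(.data$k)
  if (any(nr$n < 2)) stop_invalid("at least 2 runs per k are required")

  wide <- runs |>
    arrange(.data$k, .data$run) |>
    tidyr::pivot_wider(names_from = "k", values_from = "ln_pd",
                       names_prefix = "k")
  lmat <- as.matrix(wide[, paste0("k", ks), drop = FALSE])  # runs x k
  lp <- t(apply(lmat, 1, function(x) c(NA, diff(x))))                # L'(k)
  lpp <- t(apply(lp, 1, function(x) c(diff(x), NA)))                 # L''(k)

  out <- tibble(
    k = ks,
    n_runs = nr$n[match(ks, nr$k)],
    mean_ln_pd = unname(colMeans(lmat)),
    sd_ln_pd = unname(apply(lmat, 2, stats::sd)),
    l_prime = unname(colMeans(lp)),
    l_second = unname(colMeans(abs(lpp)))
  ) |>
    mutate(delta_k = ifelse(is.na(.data$l_second) | .data$sd_ln_pd == 0,
                            NA_real_, .data$l_second / .data$sd_ln_pd))
  zero_sd <- out$k[!is.na(out$l_second) & out$sd_ln_pd == 0]
  if (length(zero_sd) > 0) {
    warn(paste0("delta-k undefined (zero sd of Ln P(D)) at k = ",
                paste(zero_sd, collapse = ", ")))
  }
  structure(out, class = c("evanno_table", class(out)))
}

#' Membership assignment summary
#'
#' An accession is "assigned" to a cluster when its largest membership
#' proportion exceeds `threshold`. Reports per-accession assignments and the
#' assigned fraction of the panel.
#'
#' @param q Membership matrix or tibble (`accession` column optional).
#' @param threshold Assignment threshold strictly in (0, 1); default 0.8.
#' @return List with `fraction` (assigned / total) and `assignments`
#'   (tibble: `accession`, `cluster`, `max_q`, `assigned`).
#' @export
membership_summary <- function(q, threshold = 0.8) {
  threshold <- check_prob_open(threshold, "threshold")
  qm <- q_as_matrix(q)
  accession <- if (is.data.frame(q) && "accession" %in% names(q)) {
    q$accession
  } else {
    rownames(qm) %||% as.character(seq_len(nrow(qm)))
  }
  max_q <- apply(qm, 1, max)
  cluster <- max.col(qm, ties.method = "first")
  assigned <- max_q > threshold
  list(
    fraction = mean(assigned),
    assignments = tibble(accession = accession, cluster = cluster,
                         max_q = max_q, assigned = assigned)
  )
}
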