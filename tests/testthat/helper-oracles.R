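# Independent oracles used to check the package implementations.

# Scott-Knott by explicit recursion: at each node enumerate every contiguous
# 2-partition, compute the between-group sum of squares directly from group
# means, apply the likelihood-ratio test, recurse. Returns the cluster id of
# each mean in decreasing-mean order.
sk_oracle <- function(means, r, mse, df_error, alpha = 0.05) {
  y <- sort(means, decreasing = TRUE)
  cl <- integer(length(y))
  nid <- 0L
  rec <- function(idx) {
    k <- length(idx)
    if (k < 2) {
      nid <<- nid + 1L
      cl[idx] <<- nid
      return(invisible())
    }
    yi <- y[idx]
    b <- vapply(seq_len(k - 1), function(i) {
      g1 <- yi[1:i]; g2 <- yi[(i + 1):k]
      i * (mean(g1) - mean(yi))^2 + (k - i) * (mean(g2) - mean(yi))^2
    }, numeric(1))
    at <- which.max(b)              # which.max takes the leftmost maximum
    s2y <- mse / r
    sig0 <- (sum((yi - mean(yi))^2) + df_error * s2y) / (k + df_error)
    lam <- pi / (2 * (pi - 2)) * b[at] / sig0
    if (sig0 > 0 && lam > qchisq(1 - alpha, k / (pi - 2))) {
      rec(idx[1:at]); rec(idx[(at + 1):k])
    } else {
      nid <<- nid + 1L
      cl[idx] <<- nid
    }
  }
  rec(seq_along(y))
  cl
}

# dense multivariate-normal log-likelihood via Cholesky (no package)
mvn_lnl <- function(y, mean, Sigma) {
  ch <- chol(Sigma)
  r <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

# brute-force ML fit of y = X beta + u + e with Var = 2K vg + R vr,
# maximizing the exact Gaussian likelihood over (log vg, log vr)
qk_oracle_ml <- function(y, X, K, n_obs) {
  R <- diag(1 / n_obs)
  nll <- function(par) {
    S <- 2 * K * exp(par[1]) + R * exp(par[2])
    ch <- try(chol(S), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e10)
    Xt <- backsolve(ch, X, transpose = TRUE)
    yt <- backsolve(ch, y, transpose = TRUE)
    beta <- qr.solve(Xt, yt)
    -mvn_lnl(y, as.numeric(X %*% beta), S)
  }
  best <- Inf
  for (st in list(c(0, 0), c(2, -2), c(-2, 2), c(-6, 0))) {
    o <- optim(st, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  -best
}

# single-marker LOD by brute-force maximization of the two-component normal
# likelihood (grid + refinement over the two class means and common sd)
lod_oracle <- function(y, g) {
  n <- length(y)
  nll2 <- function(par) {
    mu <- ifelse(g == sort(unique(g))[1], par[1], par[2])
    -sum(dnorm(y, mu, exp(par[3]), log = TRUE))
  }
  nll0 <- function(par) -sum(dnorm(y, par[1], exp(par[2]), log = TRUE))
  o2 <- optim(c(mean(y), mean(y), log(sd(y))), nll2,
              control = list(maxit = 10000, reltol = 1e-14))
  o0 <- optim(c(mean(y), log(sd(y))), nll0,
              control = list(maxit = 10000, reltol = 1e-14))
  (o0$value - o2$value) / log(10)
}

# small complete phenotype record table built from closed-form trajectories
make_records <- function(ilc, ctrl_rate, al_rates13, al_rates35,
                         accession = "acc1", n_plants = 2) {
  rows <- list()
  for (p in seq_len(n_plants)) {
    for (trt in c("control", "Al")) {
      r13 <- if (trt == "control") ctrl_rate else al_rates13
      r35 <- if (trt == "control") ctrl_rate else al_rates35
      lens <- c(ilc, ilc + r13, ilc + 3 * r13, ilc + 3 * r13 + 2 * r35)
      rows[[length(rows) + 1]] <- data.frame(
        accession = accession, treatment = trt, rep = 1L, plant = p,
        day = c(0, 1, 3, 5), length_cm = lens)
    }
  }
  dplyr::bind_rows(rows)
}
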