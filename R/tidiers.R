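#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_text labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy and summarise fitted objects
#'
#' broom-style methods: `tidy()` returns one row per term/group/cluster and
#' `glance()` one row of model-level summaries.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name sorgal-tidiers
NULL

#' @rdname sorgal-tidiers
#' @export
tidy.qk_fit <- function(x, ...) x$fixef

#' @rdname sorgal-tidiers
#' @export
glance.qk_fit <- function(x, ...) {
  tibble(vg = x$vg, vr = x$vr, ratio = x$ratio,
         lnl_ml = x$lnl_ml, lnl_reml = x$lnl_reml,
         bic = x$bic, p = x$p, n = x$n)
}

#' @rdname sorgal-tidiers
#' @export
tidy.structure_run <- function(x, ...) {
  tidyr::pivot_longer(x$Q, -"accession", names_to = "cluster",
                      values_to = "membership")
}

#' @rdname sorgal-tidiers
#' @export
glance.structure_run <- function(x, ...) {
  tibble(k = x$k, ln_pd = x$ln_pd, model = x$model,
         burnin = x$settings$burnin, iters = x$settings$iters,
         alpha = x$settings$alpha, seed = x$settings$seed)
}

#' @rdname sorgal-tidiers
#' @export
tidy.scott_knott <- function(x, ...) as_tibble(x)

#' @rdname sorgal-tidiers
#' @export
glance.scott_knott <- function(x, ...) {
  tibble(n_groups = nrow(x), n_clusters = attr(x, "n_clusters"),
         alpha = attr(x, "alpha"))
}

#' @rdname sorgal-tidiers
#' @export
tidy.tolerance_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         proportion = x$proportion,
         cumulative = x$cumulative)
}

#' @rdname sorgal-tidiers
#' @export
tidy.rank_comparison <- function(x, ...) x$groups

#' @rdname sorgal-tidiers
#' @export
glance.rank_comparison <- function(x, ...) {
  bind_cols(x$kruskal, tibble(alpha = x$alpha))
}

#' @rdname sorgal-tidiers
#' @export
tidy.contingency_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$observed))) |>
    rlang::set_names(c("row", "col", "observed")) |>
    mutate(expected = as.vector(x$expected))
}

#' @rdname sorgal-tidiers
#' @export
glance.contingency_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Plot methods for result objects
#'
#' `autoplot()` methods returning ggplot objects: the Evanno delta-k curve,
#' the tolerance-index PCA score plot, Scott-Knott means with letter codes,
#' stacked membership bars for an admixture fit, and the BIC
#' model-comparison bars of a sequential-exclusion table.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name sorgal-autoplot
NULL

#' @rdname sorgal-autoplot
#' @export
autoplot.evanno_table <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$delta_k))
  ggplot(df, aes(x = .data$k, y = .data$delta_k)) +
    geom_line() +
    geom_point() +
    labs(x = "k (number of clusters)", y = expression(Delta * k),
         title = "Evanno model-order diagnostic") +
    theme_minimal()
}

#' @rdname sorgal-autoplot
#' @param classes Optional tibble (`accession`, `class`) to colour the PCA
#'   scores by tolerance class.
#' @export
autoplot.tolerance_pca <- function(object, classes = NULL, ...) {
  df <- object$scores
  if (!is.null(classes)) df <- left_join(df, classes, by = "accession")
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(classes)) p + geom_point(aes(colour = .data$class))
  else p + geom_point()
  p + labs(title = "Tolerance-index principal components",
           x = sprintf("PC1 (%.1f%%)", 100 * object$proportion[1]),
           y = sprintf("PC2 (%.1f%%)", 100 * object$proportion[2])) +
    theme_minimal()
}

#' @rdname sorgal-autoplot
#' @export
autoplot.scott_knott <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(group = factor(.data$group, levels = .data$group))
  ggplot(df, aes(x = .data$group, y = .data$mean,
                 fill = factor(.data$cluster))) +
    geom_col() +
    geom_text(aes(label = .data$letter), vjust = -0.4) +
    labs(x = NULL, y = "mean", fill = "cluster",
         title = "Scott-Knott homogeneous groups") +
    theme_minimal()
}

#' @rdname sorgal-autoplot
#' @export
autoplot.structure_run <- function(object, ...) {
  df <- tidy.structure_run(object)
  ggplot(df, aes(x = .data$accession, y = .data$membership,
                 fill = .data$cluster)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "membership", fill = NULL,
         title = sprintf("Admixture memberships (k = %d)", object$k)) +
    ggplot2::theme_void() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname sorgal-autoplot
#' @export
autoplot.qk_model_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(model = factor(.data$model, levels = .data$model))
  ggplot(df, aes(x = .data$model, y = .data$bic)) +
    geom_col() +
    labs(x = NULL, y = "BIC",
         title = "Q+K model comparison (sequential subpopulation exclusion)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("Admixture fit (%s)\n", x$model))
  cat(sprintf("  k = %d, accessions = %d, Ln P(D) = %.2f\n",
              x$k, nrow(x$Q), x$ln_pd))
  cat(sprintf("  sweeps: %d (burn-in %d), alpha = %g, seed = %d\n",
              x$settings$iters, x$settings$burnin, x$settings$alpha,
              x$settings$seed))
  invisible(x)
}

#' @export
print.qk_fit <- function(x, ...) {
  cat("Q+K mixed model fit\n")
  cat(sprintf("  n = %d, fixed effects: %s\n", x$n,
              paste(c("(Intercept)", x$included), collapse = ", ")))
  cat(sprintf("  Vg = %.4g, V_R = %.4g (ratio %.4g)\n", x$vg, x$vr, x$ratio))
  cat(sprintf("  lnL (ML) = %.4f, lnL (REML) = %.4f, BIC = %.4f (p = %d)\n",
              x$lnl_ml, x$lnl_reml, x$bic, x$p))
  invisible(x)
}

#' @export
print.kinship_psa <- function(x, ...) {
  cat(sprintf("Proportion-of-shared-alleles kinship: %d accessions, %d loci max\n",
              nrow(x$K), max(x$n_loci)))
  cat(sprintf("  K range [%.3f, %.3f], mean off-diagonal %.3f\n",
              min(x$K), max(x$K),
              mean(x$K[upper.tri(x$K)])))
  invisible(x)
}
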