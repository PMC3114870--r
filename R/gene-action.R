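#' Degree of dominance from parent and F1 means
#'
#' Computes the dominance effect `d = Tt - (TT + tt) / 2`, the additive
#' effect `a = (TT - tt) / 2` and the degree of dominance `d / a` from the
#' RRG means of the tolerant parent (`TT`), the sensitive recurrent parent
#' (`tt`) and the F1 hybrid (`Tt`), and assigns the mode-of-gene-action
#' category: recessive (`d/a <= -0.7`), partially recessive
#' (`-0.7 < d/a < -0.3`), additive (`-0.3 <= d/a <= +0.3`), partially
#' dominant (`+0.3 < d/a < +0.7`), dominant (`d/a >= +0.7`). The ratio is
#' reported unclamped, so over- and under-dominance (`|d/a| > 1`) are
#' surfaced.
#'
#' @param crosses Data frame with columns `TT_mean`, `tt_mean`, `Tt_mean`
#'   (one row per cross; other columns such as `family` are carried
#'   through), or three numeric scalars passed as `TT_mean`, `tt_mean`,
#'   `Tt_mean`.
#' @param tt_mean,Tt_mean Used only when `crosses` is a scalar `TT` mean.
#' @return Tibble of class `gene_action` with added columns `d`, `a`,
#'   `d_over_a` and `category`.
#' @export
#' @examples
#' estimate_gene_action(90, 10, 30)   # d/a = -0.5, partially recessive
estimate_gene_action <- function(crosses, tt_mean = NULL, Tt_mean = NULL) {
  if (!is.data.frame(crosses)) {
    crosses <- tibble(TT_mean = crosses, tt_mean = tt_mean, Tt_mean = Tt_mean)
  }
  check_cols(crosses, c("TT_mean", "tt_mean", "Tt_mean"), "crosses")
  if (any(crosses$TT_mean <= crosses$tt_mean)) {
    stop_invalid("`TT_mean` must exceed `tt_mean` for every cross (orientation)")
  }
  out <- as_tibble(crosses) |>
    mutate(
      d = .data$Tt_mean - (.data$TT_mean + .data$tt_mean) / 2,
      a = (.data$TT_mean - .data$tt_mean) / 2,
      d_over_a = .data$d / .data$a,
      category = gene_action_category(.data$d_over_a)
    )
  structure(out, class = c("gene_action", class(out)))
}

gene_action_category <- function(da) {
  factor(
    ifelse(da <= -0.7, "recessive",
    ifelse(da < -0.3, "partially recessive",
    ifelse(da <= 0.3, "additive",
    ifelse(da < 0.7, "partially dominant", "dominant")))),
    levels = c("recessive", "partially recessive", "additive",
               "partially dominant", "dominant")
  )
}

lod_from_rss <- function(rss0, rss1, n) {
  (n / 2) * log10(rss0 / rss1)
}

progeny_table <- function(family) {
  if (inherits(family, "cross_family")) family$progeny else as_tibble(family)
}

#' Single-marker linkage test in a backcross family
#'
#' Compares the null (grand-mean) model of progeny RRG against the
#' marker-mean model for one flanking marker:
#' `LOD = (n / 2) * log10(RSS0 / RSS1)`. Significance is declared at
#' `LOD >= threshold` (default 3).
#'
#' @param family A [simulate_bc1_family()] result, or a progeny data frame
#'   with the marker column (values `"H"`/`"A"`) and `rrg_percent`.
#' @param marker Name of the marker column (default `"marker1"`).
#' @param threshold LOD significance threshold (default 3).
#' @return An object of class `linkage_result`: tibble with `marker`,
#'   `position_cm` (`NA` for a single-marker test), `lod`, `significant`.
#' @export
single_marker_lod <- function(family, marker = "marker1", threshold = 3) {
  prog <- progeny_table(family)
  check_cols(prog, c(marker, "rrg_percent"), "family progeny")
  g <- prog[[marker]]
  y <- prog$rrg_percent
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("both marker classes must be present with at least 2 progeny each",
          class = "sorgal_inestimable")
  }
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  fitted <- stats::ave(y, g)
  rss1 <- sum((y - fitted)^2)
  lod <- lod_from_rss(rss0, rss1, n)
  structure(
    tibble(marker = marker, position_cm = NA_real_, lod = lod,
           significant = lod >= threshold),
    class = c("linkage_result", class(tibble())),
    threshold = threshold, n = n
  )
}

# P(QTL heterozygous | flanking marker genotypes) in a backcross,
# Haldane distances, no interference
bc_qtl_prob <- function(m1, m2, x, d12) {
  r1 <- haldane(x)
  r2 <- haldane(d12 - x)
  r12 <- haldane(d12)
  p <- numeric(length(m1))
  hh <- m1 == "H" & m2 == "H"
  ha <- m1 == "H" & m2 == "A"
  ah <- m1 == "A" & m2 == "H"
  aa <- m1 == "A" & m2 == "A"
  p[hh] <- (1 - r1) * (1 - r2) / (1 - r12)
  p[aa] <- r1 * r2 / (1 - r12)
  if (r12 > 0) {
    p[ha] <- (1 - r1) * r2 / r12
    p[ah] <- r1 * (1 - r2) / r12
  } else {
    # zero-length interval: recombinant classes cannot occur; if present in
    # data (impossible under the model) treat as uninformative
    p[ha | ah] <- 0.5
  }
  p
}

#' Simple interval mapping in a backcross family
#'
#' Scans a grid of putative QTL positions between two flanking markers. At
#' each position the conditional probability that a progeny is heterozygous
#' at the QTL given its two flanking-marker genotypes is computed with
#' Haldane-converted distances (no interference), and progeny RRG is
#' regressed on that probability (Haley-Knott regression);
#' `LOD = (n / 2) * log10(RSS0 / RSS1)`. A zero-length interval reduces to
#' the single-marker test.
#'
#' @inheritParams single_marker_lod
#' @param marker_map Length-2 cM distances of the two markers from the
#'   locus (taken from the `cross_family` object when omitted); the scan
#'   runs over `[0, sum(marker_map)]` with marker 1 at 0.
#' @param grid_step Scan step in cM (default 0.5).
#' @return An object of class `linkage_result`: tibble with `position_cm`,
#'   `lod`, `significant`; attributes `threshold`, `n`, `peak_cm` (position
#'   of the maximum LOD) and `max_lod`.
#' @export
interval_mapping_bc <- function(family, marker_map = NULL, grid_step = 0.5,
                                threshold = 3) {
  prog <- progeny_table(family)
  check_cols(prog, c("marker1", "marker2", "rrg_percent"), "family progeny")
  if (is.null(marker_map) && inherits(family, "cross_family")) {
    marker_map <- family$marker_map
  }
  if (is.null(marker_map) || length(marker_map) != 2 || any(marker_map < 0)) {
    stop_invalid("`marker_map` must be two non-negative cM distances")
  }
  if (nrow(prog) < 4) stop_invalid("at least 4 progeny are required")
  d12 <- sum(marker_map)
  y <- prog$rrg_percent
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (d12 == 0) {
    sm <- single_marker_lod(prog, "marker1", threshold = threshold)
    sm$position_cm <- 0
    return(sm)
  }
  grid <- unique(sort(c(seq(0, d12, by = grid_step), d12)))
  lod <- vapply(grid, function(x) {
    p <- bc_qtl_prob(prog$marker1, prog$marker2, x, d12)
    if (stats::var(p) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, p), y)
    lod_from_rss(rss0, sum(fit$residuals^2), n)
  }, numeric(1))
  out <- tibble(position_cm = grid, lod = lod, significant = lod >= threshold)
  structure(out, class = c("linkage_result", class(tibble())),
            threshold = threshold, n = n,
            peak_cm = grid[which.max(lod)], max_lod = max(lod))
}
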