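stop_degenerate <- function(msg) abort(msg, class = "sorgal_degenerate_denominator")

#' Relative net root growth (RNRG)
#'
#' For each accession (and each Al treatment level present), divides the mean
#' net root growth under Al over `day` days of exposure by the mean net root
#' growth of the control plants over the same period, expressed in percent.
#' Net growth per plant is its length at `day` minus its length at day 0
#' (end of acclimation). The ratio is of treatment-mean over control-mean
#' net growth (Al-treated and control plants are distinct individuals, so a
#' per-plant ratio is not defined).
#'
#' @param records Root-growth records: a data frame with columns `accession`,
#'   `treatment` (`"control"` and one or more Al labels), `rep`, `plant`,
#'   `day`, `length_cm`, one row per plant-day as produced by
#'   [simulate_root_growth()] or [read_phenotype_csv()].
#' @param day Exposure period: 3 or 5.
#' @return Tibble with columns `accession`, `treatment` (the Al label) and
#'   `rnrg` (%).
#' @export
compute_rnrg <- function(records, day = 5) {
  check_cols(records, c("accession", "treatment", "plant", "day", "length_cm"),
             "records")
  if (!day %in% records$day) stop_invalid(sprintf("no measurements at day %s", day))
  net <- records |>
    filter(.data$day %in% c(0, !!day)) |>
    tidyr::pivot_wider(names_from = "day", values_from = "length_cm",
                       names_prefix = "d") |>
    mutate(net = .data[[paste0("d", day)]] - .data$d0)
  ctrl <- net |>
    filter(.data$treatment == "control") |>
    summarise(ctrl_net = mean(.data$net), .by = "accession")
  al <- net |>
    filter(.data$treatment != "control") |>
    summarise(al_net = mean(.data$net), .by = c("accession", "treatment"))
  if (nrow(ctrl) == 0 || nrow(al) == 0) {
    stop_invalid("records must contain both control and Al-treated plants")
  }
  out <- inner_join(al, ctrl, by = "accession")
  if (any(out$ctrl_net <= 0)) {
    stop_degenerate(paste0(
      "mean control net growth is zero or negative for accession(s): ",
      paste(out$accession[out$ctrl_net <= 0], collapse = ", ")))
  }
  out |>
    transmute(.data$accession, .data$treatment,
              rnrg = 100 * .data$al_net / .data$ctrl_net) |>
    arrange(.data$accession)
}

#' Induction of root growth (IRG)
#'
#' Ratio of the daily root-growth rate between days 3 and 5 of Al exposure
#' to that between days 1 and 3. Plant lengths are averaged per accession and
#' day before the ratio is formed. Values above 1 indicate induced
#' (improving) tolerance; 1 indicates a constant growth rate.
#'
#' @inheritParams compute_rnrg
#' @return Tibble with columns `accession`, `treatment`, `irg`.
#' @export
compute_irg <- function(records) {
  check_cols(records, c("accession", "treatment", "day", "length_cm"), "records")
  al <- records |>
    filter(.data$treatment != "control", .data$day %in% c(1, 3, 5)) |>
    summarise(len = mean(.data$length_cm),
              .by = c("accession", "treatment", "day"))
  wide <- tidyr::pivot_wider(al, names_from = "day", values_from = "len",
                             names_prefix = "d")
  check_cols(wide, c("d1", "d3", "d5"), "records (Al lengths at days 1, 3, 5)")
  if (any(wide$d3 == wide$d1)) {
    stop_degenerate("day-1 to day-3 growth is zero; IRG undefined")
  }
  wide |>
    transmute(.data$accession, .data$treatment,
              irg = ((.data$d5 - .data$d3) / 2) / ((.data$d3 - .data$d1) / 2)) |>
    arrange(.data$accession)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative root growth (RRG) for segregating families
#'
#' Per-plant index used where a genetically identical control plant does not
#' exist (F1 and backcross families): growth during the five-day Al phase
#' relative to the plant's own projected control growth, i.e.
#' `RRG = 100 * (flAl - flc) / ((flc - ilc) * 5)` where `ilc` is the root
#' length at the end of acclimation, `flc` the length after one further day
#' in control solution, and `flAl` the length after five subsequent days in
#' Al.
#'
#' @param plants Data frame with per-plant columns `ilc`, `flc`, `flAl`
#'   (cm); any identifier columns are carried through.
#' @return The input tibble with an added `rrg_percent` column.
#' @export
compute_rrg <- function(plants) {
  check_cols(plants, c("ilc", "flc", "flAl"), "plants")
  if (any(plants$flc == plants$ilc)) {
    stop_degenerate("control-phase growth (flc - ilc) is zero; RRG undefined")
  }
  as_tibble(plants) |>
    mutate(rrg_percent = 100 * (.data$flAl - .data$flc) /
             ((.data$flc - .data$ilc) * 5))
}

#' Classify accessions by Al tolerance
#'
#' Deterministic rule on RNRG after five days of Al exposure: below 30%
#' sensitive, above 80% tolerant, otherwise intermediate. Values of exactly
#' 30 or 80 are classed intermediate (the defining inequalities are strict
#' on both sides, leaving the boundaries to the middle class).
#'
#' @param rnrg5d Numeric vector of RNRG values (%) at 5 days.
#' @return Factor with levels `sensitive`, `intermediate`, `tolerant`.
#' @export
#' @examples
#' classify_tolerance(c(25, 30, 55, 80, 85))
classify_tolerance <- function(rnrg5d) {
  if (any(!is.finite(rnrg5d))) stop_invalid("RNRG values must be finite")
  factor(ifelse(rnrg5d < 30, "sensitive",
                ifelse(rnrg5d > 80, "tolerant", "intermediate")),
         levels = c("sensitive", "intermediate", "tolerant"))
}

#' Aggregate visual root damage (VRD) scores
#'
#' Averages independent ordinal root-apex damage evaluations, each scored on
#' the 1 (heavily damaged) to 5 (undamaged) scale.
#'
#' @param scores Data frame with columns `accession` and `score` (integers
#'   in 1..5; typically three evaluations per accession).
#' @return Tibble with columns `accession`, `vrd` (mean score in `[1, 5]`).
#' @export
aggregate_vrd <- function(scores) {
  check_cols(scores, c("accession", "score"), "scores")
  s <- scores$score
  if (any(is.na(s)) || any(s < 1 | s > 5 | s != round(s))) {
    stop_invalid("every VRD score must be an integer in 1..5")
  }
  scores |>
    summarise(vrd = mean(.data$score), .by = "accession") |>
    arrange(.data$accession)
}

#' Per-accession tolerance profiles
#'
#' Convenience wrapper combining [compute_rnrg()] at 3 and 5 days,
#' [compute_irg()], optional [aggregate_vrd()] and [classify_tolerance()]
#' into one tibble per accession and Al treatment.
#'
#' @inheritParams compute_rnrg
#' @param vrd_scores Optional data frame for [aggregate_vrd()].
#' @return Tibble: `accession`, `treatment`, `rnrg3d`, `rnrg5d`, `irg`,
#'   optionally `vrd`, and `class`.
#' @export
tolerance_profiles <- function(records, vrd_scores = NULL) {
  out <- compute_rnrg(records, day = 3) |>
    rename(rnrg3d = "rnrg") |>
    inner_join(rename(compute_rnrg(records, day = 5), rnrg5d = "rnrg"),
               by = c("accession", "treatment")) |>
    inner_join(compute_irg(records), by = c("accession", "treatment"))
  if (!is.null(vrd_scores)) {
    out <- left_join(out, aggregate_vrd(vrd_scores), by = "accession")
  }
  mutate(out, class = classify_tolerance(.data$rnrg5d))
}

#' Scott-Knott clustering of group means
#'
#' Partitions treatment (accession) means into homogeneous groups by the
#' Scott-Knott likelihood-ratio procedure: means are sorted and recursively
#' split at the contiguous 2-partition maximising the between-group sum of
#' squares `B0`; a node is declared heterogeneous when
#' `lambda = pi / (2 * (pi - 2)) * B0 / sigma0sq` exceeds the chi-squared
#' critical value with `k / (pi - 2)` degrees of freedom at level `alpha`,
#' where `sigma0sq = (sum((y - ybar)^2) + nu * s2y) / (k + nu)`,
#' `s2y = mse / r` and `nu` is the error degrees of freedom. Ties in `B0`
#' are broken toward the leftmost split.
#'
#' @param means Data frame with columns `group` and `mean`, or a named
#'   numeric vector of means.
#' @param r Replicates per group (positive scalar).
#' @param mse Mean squared error from the ANOVA (>= 0).
#' @param df_error Error degrees of freedom (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `scott_knott`: tibble with columns `group`,
#'   `mean`, `cluster` (1 = highest-mean cluster) and `letter`, plus
#'   attributes `alpha` and `n_clusters`.
#' @export
scott_knott <- function(means, r, mse, df_error, alpha = 0.05) {
  if (is.numeric(means) && !is.data.frame(means)) {
    means <- tibble(group = names(means) %||% as.character(seq_along(means)),
                    mean = as.numeric(means))
  }
  check_cols(means, c("group", "mean"), "means")
  if (!is.numeric(r) || r <= 0) stop_invalid("`r` (replicates) must be positive")
  if (mse < 0) stop_invalid("`mse` must be non-negative")
  if (df_error < 1) stop_invalid("`df_error` must be at least 1")
  alpha <- check_prob_open(alpha, "alpha")

  ord <- order(means$mean, decreasing = TRUE)
  y <- means$mean[ord]
  nu <- df_error
  s2y <- mse / r
  cluster <- integer(length(y))
  next_id <- 0L

  assign_cluster <- function(idx) {
    next_id <<- next_id + 1L
    cluster[idx] <<- next_id
  }

  recurse <- function(idx) {
    k <- length(idx)
    if (k < 2) {
      assign_cluster(idx)
      return(invisible())
    }
    yi <- y[idx]
    split <- sk_best_split(yi)
    ybar <- mean(yi)
    sigma0sq <- (sum((yi - ybar)^2) + nu * s2y) / (k + nu)
    if (sigma0sq <= 0) {
      # all means identical and no error variance: homogeneous by definition
      assign_cluster(idx)
      return(invisible())
    }
    lambda <- pi / (2 * (pi - 2)) * split$b0 / sigma0sq
    crit <- stats::qchisq(1 - alpha, df = k / (pi - 2))
    if (lambda > crit) {
      recurse(idx[seq_len(split$at)])
      recurse(idx[(split$at + 1):k])
    } else {
      assign_cluster(idx)
    }
  }
  recurse(seq_along(y))

  letters_vec <- make_letters(cluster)
  out <- tibble(group = means$group[ord], mean = y,
                cluster = cluster, letter = letters_vec)
  structure(out, class = c("scott_knott", class(out)),
            alpha = alpha, n_clusters = next_id)
}

# best contiguous 2-partition by between-group sum of squares;
# leftmost split wins ties
sk_best_split <- function(y) {
  k <- length(y)
  tot <- sum(y)
  b0 <- -Inf
  at <- 1L
  for (i in seq_len(k - 1)) {
    s1 <- sum(y[1:i])
    s2 <- tot - s1
    b <- s1^2 / i + s2^2 / (k - i) - tot^2 / k
    if (b > b0 + 1e-12) {
      b0 <- b
      at <- i
    }
  }
  list(b0 = b0, at = at)
}

make_letters <- function(cluster) {
  lab <- letters[((cluster - 1L) %% 26L) + 1L]
  reps <- (cluster - 1L) %/% 26L + 1L
  vapply(seq_along(lab), function(i) paste(rep(lab[i], reps[i]), collapse = ""),
         character(1))
}

#' Principal component analysis of tolerance indices
#'
#' PCA of per-accession RNRG at 3 days, RNRG at 5 days and IRG after
#' centring and scaling each variable to unit variance (i.e. an
#' eigendecomposition of their correlation matrix). Component signs follow a
#' deterministic convention: within each component the largest-magnitude
#' loading is made positive.
#'
#' @param profiles Data frame with an `accession` column and the numeric
#'   index columns named in `vars`.
#' @param vars Character vector of index columns (default
#'   `c("rnrg3d", "rnrg5d", "irg")`).
#' @return An object of class `tolerance_pca`: list with `eigenvalues`,
#'   `proportion`, `cumulative` (variance shares), `loadings` (variables x
#'   components) and `scores` (tibble of accession scores on the
#'   standardized scale).
#' @export
pca_indices <- function(profiles, vars = c("rnrg3d", "rnrg5d", "irg")) {
  check_cols(profiles, c("accession", vars), "profiles")
  x <- as.matrix(profiles[, vars])
  if (nrow(x) < 3) stop_invalid("at least 3 accessions are required")
  if (any(!is.finite(x))) stop_invalid("all index values must be finite")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_invalid(paste0("zero-variance variable(s): ",
                        paste(vars[sds == 0], collapse = ", ")))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  ev <- fit$sdev^2
  out <- list(
    eigenvalues = ev,
    proportion = ev / length(vars),
    cumulative = cumsum(ev) / length(vars),
    loadings = rot,
    scores = bind_cols(tibble(accession = profiles$accession),
                       as_tibble(scores))
  )
  structure(out, class = "tolerance_pca")
}
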