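#' Simulate differentiated subpopulation allele frequencies
#'
#' Draws per-subpopulation allele frequencies for a set of multi-allelic SSR
#' loci under a Balding-Nichols-style model: an ancestral frequency vector is
#' drawn for each locus from a symmetric Dirichlet, and each subpopulation's
#' vector is drawn from a Dirichlet centred on the ancestral vector with
#' concentration `(1 - F) / F`, so that for any allele with ancestral
#' frequency `p` the across-subpopulation variance is `F * p * (1 - p)`.
#'
#' @param k Number of subpopulations (>= 1).
#' @param loci_spec Data frame with columns `locus` (character) and
#'   `n_alleles` (positive integers): the allele-size alphabet size per locus.
#' @param F Differentiation parameter, strictly in (0, 1). Larger values give
#'   more divergent subpopulations.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return An object of class `allele_freq_set`: a list with elements
#'   `k`, `F`, `loci` (tibble of locus names, allele counts and allele sizes
#'   in base pairs) and `freq` (tibble with columns `locus`, `allele_bp`,
#'   `ancestral`, `pop1` .. `popk`). Every frequency column sums to 1 within
#'   each locus.
#' @export
#' @examples
#' fs <- simulate_subpop_frequencies(
#'   k = 2, loci_spec = data.frame(locus = c("L1", "L2"), n_alleles = c(4, 6)),
#'   F = 0.3, seed = 1)
#' fs$freq
simulate_subpop_frequencies <- function(k, loci_spec, F, seed = 1L) {
  k <- check_count(k, "k")
  check_cols(loci_spec, c("locus", "n_alleles"), "loci_spec")
  if (any(loci_spec$n_alleles < 1 | loci_spec$n_alleles != round(loci_spec$n_alleles))) {
    stop_invalid("every allele count in `loci_spec` must be a positive integer")
  }
  if (!is.numeric(F) || length(F) != 1L || is.na(F) || F <= 0 || F >= 1) {
    stop_invalid("`F` must lie strictly in (0, 1)")
  }
  withr_seed(seed)
  conc <- (1 - F) / F
  loci <- as_tibble(loci_spec) |>
    mutate(
      # dinucleotide-repeat ladder of fragment sizes per locus
      base_bp = sample(80:280, dplyr::n(), replace = TRUE),
      alleles_bp = map2(.data$base_bp, .data$n_alleles,
                        function(b, m) as.integer(b + 2 * (0:(m - 1))))
    )
  freq <- purrr::pmap(
    list(loci$locus, loci$alleles_bp, loci$n_alleles),
    function(loc, sizes, m) {
      anc <- as.numeric(rdirichlet(1, rep(1, m)))
      pops <- vapply(seq_len(k), function(j) {
        if (m == 1L) return(1)
        as.numeric(rdirichlet(1, anc * conc))
      }, numeric(m))
      pops <- matrix(pops, nrow = m, ncol = k)
      colnames(pops) <- paste0("pop", seq_len(k))
      tibble(locus = loc, allele_bp = sizes, ancestral = anc) |>
        bind_cols(as_tibble(pops))
    }
  ) |> bind_rows()
  structure(
    list(k = k, F = F, loci = select(loci, "locus", "n_alleles", "alleles_bp"),
         freq = freq, seed = as.integer(seed)),
    class = "allele_freq_set"
  )
}

# seed handling kept local so simulations never disturb the caller's RNG state
withr_seed <- function(seed) {
  seed <- check_count(seed, "seed", min = 0L)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  set.seed(seed)
  invisible(old)
}

#' Simulate an admixed inbred accession panel with a tolerance locus
#'
#' Builds a genotype panel of inbred accessions drawn from `k` admixed
#' subpopulations, together with the true membership matrix and the true
#' genotype at a biallelic major tolerance locus. Each accession's membership
#' row is drawn from a Dirichlet with shape `concentration` in every
#' component plus 1 in its home subpopulation, so `concentration -> 0` gives
#' one-hot (pure) membership. Per locus, one allele is drawn from the
#' membership-weighted mixture of subpopulation frequencies and, when
#' `selfing = TRUE`, duplicated (fully homozygous accessions, as in inbred
#' sorghum landraces). The tolerance genotype is `TT` with probability equal
#' to the membership-weighted tolerant-allele frequency, else `tt`.
#'
#' @param freqs An [simulate_subpop_frequencies()] result.
#' @param n_per_subpop Integer vector of length `k`: accessions per home
#'   subpopulation.
#' @param admixture_concentration Positive scalar controlling admixture;
#'   small values give nearly pure accessions.
#' @param selfing If `TRUE` (default) accessions are fully homozygous.
#' @param tolerance_locus_freqs Length-`k` vector of tolerant-allele
#'   frequencies per subpopulation (values in `[0, 1]`).
#' @param seed Integer seed.
#' @return An object of class `true_panel`: list with `genotypes` (long
#'   tibble: `accession`, `locus`, `allele1_bp`, `allele2_bp`), `q_true`
#'   (tibble: `accession`, `subpop`, `q1..qk`), `tolerance_genotype` (tibble:
#'   `accession`, `genotype` in `{"TT","tt"}`), `freqs` and `seed`.
#' @export
simulate_panel <- function(freqs, n_per_subpop, admixture_concentration = 0.1,
                           selfing = TRUE, tolerance_locus_freqs = NULL,
                           seed = 1L) {
  stopifnot(inherits(freqs, "allele_freq_set"))
  k <- freqs$k
  if (length(n_per_subpop) != k) {
    stop_invalid("`n_per_subpop` must have one entry per subpopulation")
  }
  if (!is.numeric(admixture_concentration) || admixture_concentration <= 0) {
    stop_invalid("`admixture_concentration` must be positive")
  }
  if (is.null(tolerance_locus_freqs)) tolerance_locus_freqs <- rep(0, k)
  if (length(tolerance_locus_freqs) != k ||
      any(tolerance_locus_freqs < 0 | tolerance_locus_freqs > 1)) {
    stop_invalid("`tolerance_locus_freqs` must be k frequencies in [0, 1]")
  }
  withr_seed(seed)
  n <- sum(n_per_subpop)
  home <- rep(seq_len(k), times = n_per_subpop)
  acc <- sprintf("acc%03d", seq_len(n))

  q <- matrix(vapply(home, function(s) {
    alpha <- rep(admixture_concentration, k)
    alpha[s] <- alpha[s] + 1
    as.numeric(rdirichlet(1, alpha))
  }, numeric(k)), nrow = n, ncol = k, byrow = TRUE)
  colnames(q) <- paste0("q", seq_len(k))

  popcols <- paste0("pop", seq_len(k))
  geno <- freqs$freq |>
    tidyr::nest(tab = -"locus") |>
    mutate(drawn = map(.data$tab, function(tab) {
      p <- as.matrix(tab[, popcols, drop = FALSE])   # m x k
      mix <- q %*% t(p)                              # n x m mixture freqs
      a1 <- apply(mix, 1, function(w) sample(tab$allele_bp, 1, prob = w))
      a2 <- if (selfing) a1 else {
        apply(mix, 1, function(w) sample(tab$allele_bp, 1, prob = w))
      }
      tibble(accession = acc, allele1_bp = as.integer(pmin(a1, a2)),
             allele2_bp = as.integer(pmax(a1, a2)))
    })) |>
    select("locus", "drawn") |>
    tidyr::unnest("drawn") |>
    select("accession", "locus", "allele1_bp", "allele2_bp") |>
    arrange(.data$accession, .data$locus)

  f_mix <- as.numeric(q %*% tolerance_locus_freqs)
  tol <- ifelse(stats::runif(n) < f_mix, "TT", "tt")

  structure(
    list(
      genotypes = geno,
      q_true = bind_cols(tibble(accession = acc, subpop = home), as_tibble(q)),
      tolerance_genotype = tibble(accession = acc, genotype = tol),
      freqs = freqs, selfing = selfing, seed = as.integer(seed)
    ),
    class = "true_panel"
  )
}

#' Default root-growth simulation parameters
#'
#' Study-scale defaults for [simulate_root_growth()]: seminal roots growing
#' ~1 cm/day in control solution from a ~3 cm acclimation length; under Al
#' the tolerant genotype grows at 75% of its control rate for days 0-3 and at
#' 100% for days 3-5 (the induction dynamic, IRG ~ 1.33, RNRG5d ~ 85%), while
#' the sensitive genotype is strongly and increasingly inhibited
#' (RNRG5d ~ 26%, IRG ~ 0.67). Measurement noise is 0.25 cm per reading.
#'
#' @return A named list understood by [simulate_root_growth()].
#' @export
default_growth_params <- function() {
  list(
    ilc_mean = 3, ilc_sd = 0.3,
    rate_mean = 1.0, rate_sd = 0.15,
    m1 = c(TT = 0.75, tt = 0.30),
    m2 = c(TT = 1.00, tt = 0.20),
    noise_sd = 0.25
  )
}

#' Simulate hydroponic root-growth records for a panel
#'
#' Generates per-plant root lengths at the end of acclimation (day 0) and at
#' days 1, 3 and 5 under control and Al treatments. Each plant draws a daily
#' control growth rate; Al-treated plants grow at `rate * m1` for days 0-3
#' and `rate * m2` for days 3-5, with the multipliers set by the accession's
#' tolerance genotype. Pre-noise trajectories accumulate monotonically;
#' Gaussian measurement noise is added to the recorded lengths only.
#'
#' @param panel A [simulate_panel()] result.
#' @param growth_params List as returned by [default_growth_params()].
#' @param n_plants Plants per replicate per treatment (default 7).
#' @param reps Replicates (default 2).
#' @param seed Integer seed.
#' @return A tibble of root-growth records: `accession`, `treatment`
#'   (`"control"` or `"Al"`), `rep`, `plant`, `day` (0, 1, 3, 5),
#'   `length_cm`.
#' @export
simulate_root_growth <- function(panel, growth_params = default_growth_params(),
                                 n_plants = 7, reps = 2, seed = 1L) {
  stopifnot(inherits(panel, "true_panel"))
  gp <- utils::modifyList(default_growth_params(), growth_params)
  n_plants <- check_count(n_plants, "n_plants")
  reps <- check_count(reps, "reps")
  if (gp$noise_sd < 0 || gp$rate_sd < 0 || gp$ilc_sd < 0) {
    stop_invalid("standard deviations must be non-negative")
  }
  if (gp$rate_mean <= 0) stop_invalid("control growth rate mean must be positive")
  if (any(c(gp$m1, gp$m2) < 0)) stop_invalid("Al multipliers must be non-negative")
  withr_seed(seed)

  days <- c(0, 1, 3, 5)
  grid <- tidyr::expand_grid(
    panel$tolerance_genotype,
    treatment = c("control", "Al"),
    rep = seq_len(reps),
    plant = seq_len(n_plants)
  ) |>
    mutate(
      ilc = pmax(0.5, stats::rnorm(dplyr::n(), gp$ilc_mean, gp$ilc_sd)),
      rate = pmax(0.05, stats::rnorm(dplyr::n(), gp$rate_mean, gp$rate_sd)),
      mult1 = ifelse(.data$treatment == "Al", gp$m1[.data$genotype], 1),
      mult2 = ifelse(.data$treatment == "Al", gp$m2[.data$genotype], 1)
    )
  out <- tidyr::expand_grid(grid, day = days) |>
    mutate(
      true_len = .data$ilc + .data$rate * .data$mult1 * pmin(.data$day, 3) +
        .data$rate * .data$mult2 * pmax(.data$day - 3, 0),
      length_cm = pmax(0, .data$true_len +
                         stats::rnorm(dplyr::n(), 0, gp$noise_sd))
    ) |>
    select("accession", "treatment", "rep", "plant", "day", "length_cm") |>
    arrange(.data$accession, .data$treatment, .data$rep, .data$plant, .data$day)
  out
}

#' Simulate a backcross (BC1F1) family segregating at the tolerance locus
#'
#' Progeny genotypes at the tolerance locus segregate 1:1
#' (heterozygous `Tt` vs homozygous-recurrent `tt`); two flanking markers are
#' derived by independent recombination with Haldane-converted map
#' distances. Progeny relative root growth (RRG, %) equals the genotype mean
#' plus Gaussian noise, where the `Tt` mean is the midparent value plus the
#' dominance deviation `d = (d/a) * a`, `a = (TT_mean - tt_mean) / 2`.
#'
#' @param TT_mean,tt_mean RRG means (%) of the tolerant and sensitive
#'   (recurrent) parents; `TT_mean` must exceed `tt_mean`.
#' @param d_over_a Degree of dominance of the tolerant allele.
#' @param n_progeny Number of progeny (>= 2).
#' @param marker_map Length-2 non-negative numeric: cM distances of the left
#'   and right flanking markers from the locus.
#' @param sigma RRG noise standard deviation (percentage points).
#' @param seed Integer seed.
#' @param family Family label.
#' @return An object of class `cross_family`: list with `progeny` (tibble:
#'   `family`, `progeny`, `genotype`, `marker1`, `marker2` with `"H"` =
#'   heterozygous, `"A"` = homozygous recurrent, `rrg_percent`), `parents`
#'   (tibble: `family`, `TT_mean`, `tt_mean`, `Tt_mean`) and `marker_map`.
#' @export
simulate_bc1_family <- function(TT_mean, tt_mean, d_over_a, n_progeny,
                                marker_map = c(0.2, 0.2), sigma = 5,
                                seed = 1L, family = "BC1F1") {
  if (!(TT_mean > tt_mean)) {
    stop_invalid("`TT_mean` must exceed `tt_mean` (orientation undefined otherwise)")
  }
  n_progeny <- check_count(n_progeny, "n_progeny", min = 2L)
  if (length(marker_map) != 2 || any(marker_map < 0)) {
    stop_invalid("`marker_map` must be two non-negative cM distances")
  }
  if (sigma < 0) stop_invalid("`sigma` must be non-negative")
  withr_seed(seed)

  a <- (TT_mean - tt_mean) / 2
  d <- d_over_a * a
  Tt_mean <- (TT_mean + tt_mean) / 2 + d

  geno <- ifelse(stats::runif(n_progeny) < 0.5, "H", "A")  # Tt vs tt
  flip <- function(g, cm) {
    r <- haldane(cm)
    rec <- stats::runif(length(g)) < r
    ifelse(rec, ifelse(g == "H", "A", "H"), g)
  }
  m1 <- flip(geno, marker_map[1])
  m2 <- flip(geno, marker_map[2])
  mu <- ifelse(geno == "H", Tt_mean, tt_mean)
  rrg <- mu + stats::rnorm(n_progeny, 0, sigma)

  structure(
    list(
      progeny = tibble(
        family = family, progeny = sprintf("p%04d", seq_len(n_progeny)),
        genotype = ifelse(geno == "H", "Tt", "tt"),
        marker1 = m1, marker2 = m2, rrg_percent = rrg
      ),
      parents = tibble(family = family, TT_mean = TT_mean, tt_mean = tt_mean,
                       Tt_mean = Tt_mean),
      marker_map = marker_map, d_over_a = d_over_a, sigma = sigma,
      seed = as.integer(seed)
    ),
    class = "cross_family"
  )
}

#' Study-scale default panel specification
#'
#' Default simulation conditions emulating a cultivated-sorghum diversity
#' panel: 254 inbred accessions in six subpopulations (sizes 47, 58, 23, 43,
#' 54, 29), 38 multi-allelic SSR loci, Balding-Nichols differentiation
#' `F = 0.3`, and a rare major tolerance locus whose tolerant-allele
#' frequency is enriched in subpopulations 1, 3 and 6 and absent from
#' subpopulation 5 (overall expected tolerant fraction ~6%).
#'
#' @param seed Integer seed driving every draw.
#' @param n_loci Number of SSR loci (default 38).
#' @return A list with `freqs`, `panel`, `records` (root-growth tibble) and
#'   the generating parameters.
#' @export
simulate_study_panel <- function(seed = 20110614, n_loci = 38) {
  withr_seed(seed)
  # alphabet sizes drawn so that OBSERVED allele counts in a 254-accession
  # panel emulate a diverse SSR kit (~13 observed alleles per locus, range
  # 2-29; rare alleles in large alphabets go unseen)
  n_alleles <- pmin(29L, pmax(2L, stats::rpois(n_loci, 17)))
  loci_spec <- tibble(locus = sprintf("SSR%02d", seq_len(n_loci)),
                      n_alleles = as.integer(n_alleles))
  n_per_subpop <- c(47L, 58L, 23L, 43L, 54L, 29L)
  tol_freqs <- c(0.10, 0.04, 0.13, 0.02, 0.00, 0.17)
  freqs <- simulate_subpop_frequencies(6, loci_spec, F = 0.3, seed = seed + 1L)
  panel <- simulate_panel(freqs, n_per_subpop, admixture_concentration = 0.05,
                          selfing = TRUE, tolerance_locus_freqs = tol_freqs,
                          seed = seed + 2L)
  records <- simulate_root_growth(panel, seed = seed + 3L)
  list(freqs = freqs, panel = panel, records = records,
       n_per_subpop = n_per_subpop, tolerance_locus_freqs = tol_freqs,
       seed = as.integer(seed))
}
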