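#' Default pipeline configuration
#'
#' Returns the full configuration list accepted by [run_pipeline()]. Every
#' stochastic stage carries its own seed derived from the top-level `seed`;
#' unknown keys anywhere in a supplied configuration are rejected by
#' [validate_config()].
#'
#' @param seed Top-level integer seed.
#' @return Nested named list of stage toggles and parameters.
#' @export
default_config <- function(seed = 20110614) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, phenotype = TRUE, diversity = TRUE,
                  structure = TRUE, evanno = FALSE, gene_action = TRUE,
                  associate = TRUE),
    simulate = list(n_loci = 38L),
    phenotype = list(sensitive_below = 30, tolerant_above = 80,
                     scott_knott_alpha = 0.05),
    structure = list(k = 6L, burnin = 500L, iters = 2500L, alpha = 1,
                     lambda = 1),
    evanno = list(k_range = 2:5, n_runs = 2L, burnin = 200L, iters = 1200L),
    gene_action = list(
      families = list(
        list(family = "F1_recessive", TT_mean = 90, tt_mean = 10,
             d_over_a = -0.5, n_progeny = 150),
        list(family = "F1_additive", TT_mean = 90, tt_mean = 10,
             d_over_a = 0, n_progeny = 150),
        list(family = "F1_dominant", TT_mean = 90, tt_mean = 10,
             d_over_a = 0.9, n_progeny = 150)
      ),
      marker_map = c(5, 5), sigma = 5, grid_step = 0.5, lod_threshold = 3
    ),
    association = list(trait = "rnrg5d", alpha = 0.05,
                       membership_threshold = 0.8, drop_dependency = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration against the schema implied by
#' [default_config()]: unknown keys are rejected with the offending key
#' named, and every stochastic stage must have a seed (inherited from the
#' top-level `seed`).
#'
#' @param config Nested named list.
#' @return The merged (defaults-filled) configuration, invisibly usable.
#' @export
validate_config <- function(config) {
  template <- default_config()
  walk_keys <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown) > 0) {
      stop_invalid(paste0("unknown configuration key(s): ",
                          paste(paste0(path, unknown), collapse = ", ")))
    }
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]])) &&
          nm != "families") {
        if (!is.list(cfg[[nm]])) {
          stop_invalid(paste0("configuration key `", path, nm,
                              "` must be a list"))
        }
        walk_keys(cfg[[nm]], tpl[[nm]], paste0(path, nm, "."))
      }
    }
  }
  walk_keys(config, template, "")
  merged <- utils::modifyList(template, config)
  # modifyList cannot merge the unnamed families list; take it verbatim
  if (!is.null(config$gene_action$families)) {
    merged$gene_action$families <- config$gene_action$families
  }
  if (is.null(merged$seed)) stop_invalid("configuration must carry a `seed`")
  merged
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages in dependency order: simulate the panel and
#' phenotypes, compute tolerance profiles and the index PCA, SSR diversity
#' and kinship, admixture clustering (optionally an Evanno scan over a k
#' range), gene-action and backcross linkage analysis, and the
#' structured-association stage (Kruskal-Wallis + lsd letters, Q+K
#' sequential exclusion, structure R-squared, and a subpopulation x
#' tolerance contingency test). All randomness flows from the configuration
#' seed, so two runs with equal configurations are identical. When
#' `out_dir` is given, the report tables are written as CSV files, each
#' carrying the configuration hash and seed in a comment line.
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are filled with defaults after validation.
#' @param out_dir Optional directory for the report CSV files.
#' @param config_path Optional path to a YAML configuration file, merged
#'   over the defaults (ignored when `config` is supplied).
#' @return A list of result objects and report tibbles: `panel`,
#'   `profiles`, `pca`, `diversity`, `kinship`, `structure_fit`, `evanno`,
#'   `gene_action`, `association`, `report` (named list of the written
#'   tables) and `log` (per-stage timings).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         config_path = NULL) {
  if (!is.null(config_path) && missing(config)) {
    config <- yaml::read_yaml(config_path)
  }
  cfg <- validate_config(config)
  hash <- rlang::hash(cfg)
  prov <- sprintf("sorgal config_hash=%s seed=%d", hash, cfg$seed)
  log <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log[[stage]] <<- tibble(stage = stage,
                            seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  res <- list(config = cfg, config_hash = hash)
  report <- list()

  if (!cfg$stages$simulate) {
    stop_invalid("pipeline currently requires the synthetic stage enabled")
  }
  sim <- timed("simulate",
               simulate_study_panel(seed = cfg$seed,
                                    n_loci = cfg$simulate$n_loci))
  res$panel <- sim$panel
  res$records <- sim$records

  if (cfg$stages$phenotype) {
    res$profiles <- timed("phenotype", tolerance_profiles(sim$records))
    res$pca <- pca_indices(res$profiles)
    class_tab <- res$profiles |> count(.data$class, name = "n_accessions")
    report$tolerance_table <- res$profiles
    report$tolerance_classes <- class_tab
  }

  if (cfg$stages$diversity) {
    res$diversity <- timed("diversity", allele_stats(sim$panel$genotypes))
    res$kinship <- kinship_psa(sim$panel$genotypes)
    report$diversity_table <- res$diversity$per_locus
  }

  if (cfg$stages$structure) {
    res$structure_fit <- timed("structure", fit_admixture(
      sim$panel$genotypes, k = cfg$structure$k,
      burnin = cfg$structure$burnin, iters = cfg$structure$iters,
      alpha = cfg$structure$alpha, lambda = cfg$structure$lambda,
      seed = cfg$seed + 11L))
    ms <- membership_summary(res$structure_fit$Q,
                             cfg$association$membership_threshold)
    res$membership <- ms
    report$q_matrix <- res$structure_fit$Q
    report$q_summary <- ms$assignments
  }

  if (cfg$stages$evanno) {
    runs <- timed("evanno", {
      grid <- tidyr::expand_grid(k = cfg$evanno$k_range,
                                 run = seq_len(cfg$evanno$n_runs))
      grid$ln_pd <- purrr::pmap_dbl(grid, function(k, run) {
        fit_admixture(sim$panel$genotypes, k = k,
                      burnin = cfg$evanno$burnin, iters = cfg$evanno$iters,
                      seed = cfg$seed + 100L * k + run)$ln_pd
      })
      grid
    })
    res$evanno <- evanno_delta_k(runs)
    report$evanno_table <- as_tibble(res$evanno)
  }

  if (cfg$stages$gene_action) {
    ga <- timed("gene_action", {
      purrr::imap(cfg$gene_action$families, function(fam, i) {
        bc <- simulate_bc1_family(
          TT_mean = fam$TT_mean, tt_mean = fam$tt_mean,
          d_over_a = fam$d_over_a, n_progeny = fam$n_progeny,
          marker_map = cfg$gene_action$marker_map,
          sigma = cfg$gene_action$sigma,
          seed = cfg$seed + 200L + i, family = fam$family)
        im <- interval_mapping_bc(bc, grid_step = cfg$gene_action$grid_step,
                                  threshold = cfg$gene_action$lod_threshold)
        est <- estimate_gene_action(bc$parents)
        mutate(est, true_d_over_a = fam$d_over_a,
               max_lod = attr(im, "max_lod"),
               peak_cm = attr(im, "peak_cm"),
               significant = attr(im, "max_lod") >= cfg$gene_action$lod_threshold)
      }) |> bind_rows()
    })
    res$gene_action <- ga
    report$gene_action_table <- ga
  }

  if (cfg$stages$associate) {
    if (is.null(res$profiles) || is.null(res$kinship) ||
        is.null(res$structure_fit)) {
      stop_invalid("association stage requires phenotype, diversity and structure stages")
    }
    res$association <- timed("associate", {
      trait <- cfg$association$trait
      pheno <- res$profiles |>
        transmute(.data$accession, value = .data[[trait]], n_obs = 14)
      qhat <- res$structure_fit$Q
      sp <- res$membership$assignments |>
        transmute(.data$accession, subpop = paste0("Q", .data$cluster))
      kw_data <- inner_join(pheno, sp, by = "accession")
      lsd <- nonparametric_lsd(kw_data, "value", "subpop",
                               alpha = cfg$association$alpha)
      excl <- sequential_exclusion(pheno, qhat, res$kinship, trait = "value",
                                   drop_dependency = cfg$association$drop_dependency)
      incl <- setdiff(grep("^q", names(qhat), value = TRUE),
                      attr(excl, "drop_dependency"))
      r2 <- structure_r2(pheno, qhat[, c("accession", incl)], trait = "value")
      cls <- res$profiles |>
        inner_join(sp, by = "accession") |>
        mutate(tolerance = ifelse(.data$class == "sensitive",
                                  "sensitive", "tolerant_or_intermediate"))
      ct <- table(cls$subpop, cls$tolerance)
      chi <- if (all(rowSums(ct) > 0) && all(colSums(ct) > 0) && ncol(ct) > 1) {
        chi_square_independence(ct)
      } else NULL
      list(lsd = lsd, exclusion = excl, structure_r2 = r2, contingency = chi)
    })
    report$association_bic_table <- as_tibble(res$association$exclusion)
    report$rank_table <- res$association$lsd$groups
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      write_pipeline_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         provenance = prov)
    }
  }
  res$report <- report
  res$log <- bind_rows(log)
  res
}
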