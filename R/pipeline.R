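# ---- full-pipeline orchestration --------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes the stages of a germplasm association study in dependency order
#' -- simulate (or load), diversity, structure, kinship, LD, phenotype
#' statistics, association scan, allele mining -- writing each stage's
#' outputs as delimited text/JSON under `out_dir` together with a manifest
#' recording parameters, the seed and a content hash per file. A rerun with
#' the same configuration and seed is byte-identical for deterministic
#' stages; by default a stage whose outputs already exist is skipped unless
#' one of its upstream stages reran (`force = TRUE` reruns everything).
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `seed` (required whenever any stochastic stage runs); either `simulate`
#'   (a list of [sim_config()] arguments) or `inputs` (paths `genotypes`,
#'   `map`, `phenotypes`, `metadata`); optional `stages` (character subset
#'   of `c("simulate","diversity","structure","kinship","ld","pheno",
#'   "assoc","alleles")`); optional per-stage parameter lists `structure`
#'   (`k_range`, `n_replicates`, `min_spacing_cM`), `ld` (`n_perm`,
#'   `rare_threshold`, `alpha`), `assoc` (`alpha`, `env_alpha`, `min_env`,
#'   `rare_policy`), `alleles` (`objectives`, `min_carriers`,
#'   `high_freq_threshold`).
#' @param out_dir Output directory (created if needed).
#' @param force Rerun stages whose outputs already exist.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages_all <- c("simulate", "diversity", "structure", "kinship", "ld",
                  "pheno", "assoc", "alleles")
  stages <- config$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown) > 0) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  stochastic <- intersect(stages, c("simulate", "structure", "ld"))
  if (length(stochastic) > 0 && is.null(config$seed)) {
    abort(paste0("config$seed is required for stochastic stage(s): ",
                 paste(stochastic, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- function(...) file.path(out_dir, ...)
  manifest <- list(seed = config$seed, stages = list())
  reran <- character(0)

  run_stage <- function(name, outputs, fun) {
    if (!name %in% stages) return(invisible(NULL))
    up_to_date <- all(file.exists(paths(outputs))) && length(reran) == 0L
    if (up_to_date && !force) {
      inform(paste0("pipeline: stage '", name, "' up to date; skipping"))
    } else {
      inform(paste0("pipeline: running stage '", name, "'"))
      fun()
      reran <<- c(reran, name)
    }
    manifest$stages[[name]] <<- list(
      outputs = as.list(setNames(unname(tools::md5sum(paths(outputs))),
                                 outputs)),
      rerun = name %in% reran
    )
  }

  # --- inputs ----------------------------------------------------------------
  sim <- NULL
  run_stage("simulate",
            c("genotypes.tsv", "map.tsv", "phenotypes.tsv", "metadata.tsv",
              "truth.json"),
            function() {
    cfg <- do.call(sim_config,
                   c(config$simulate %||% list(),
                     if (is.null((config$simulate %||% list())$seed))
                       list(seed = config$seed)))
    sim <<- simulate_panel(cfg)
    write_genotypes(sim$panel, paths("genotypes.tsv"))
    write_genetic_map(sim$panel$map, paths("map.tsv"))
    write_phenotypes(sim$pheno, paths("phenotypes.tsv"))
    write_accession_meta(sim$meta, paths("metadata.tsv"))
    jsonlite::write_json(list(
      subpop = as.list(sim$truth$subpop),
      qtl = sim$truth$qtl,
      trait_truth = sim$truth$trait_truth
    ), paths("truth.json"), auto_unbox = TRUE, digits = NA)
  })

  load_panel <- function() {
    if ("simulate" %in% stages) {
      if (is.null(sim)) {
        # stage was skipped as up to date: reload from its outputs
        return(read_genotypes(paths("genotypes.tsv"),
                              map = paths("map.tsv"),
                              meta = paths("metadata.tsv")))
      }
      return(sim$panel)
    }
    inp <- config$inputs
    if (is.null(inp)) abort("stage needs a panel: provide `simulate` or `inputs`")
    read_genotypes(inp$genotypes, map = inp$map, meta = inp$metadata)
  }
  load_pheno <- function() {
    if ("simulate" %in% stages) {
      if (is.null(sim)) return(read_phenotypes(paths("phenotypes.tsv")))
      return(sim$pheno)
    }
    read_phenotypes(config$inputs$phenotypes)
  }

  panel <- if (any(c("diversity", "structure", "kinship", "ld", "assoc",
                     "alleles") %in% stages)) {
    filter_markers(load_panel(), config$max_missing_rate %||% 0.10)
  } else NULL
  pheno <- if (any(c("pheno", "assoc", "alleles") %in% stages)) {
    load_pheno()
  } else NULL

  # --- diversity -------------------------------------------------------------
  run_stage("diversity", c("diversity_per_locus.tsv", "diversity_groups.tsv"),
            function() {
    div <- locus_diversity(panel)
    div$rare_alleles <- vapply(div$rare_alleles, paste, "", collapse = ",")
    div$unique_alleles <- vapply(div$unique_alleles, paste, "", collapse = ",")
    readr::write_tsv(div, paths("diversity_per_locus.tsv"))
    grp <- diversity_by_group(panel)
    readr::write_tsv(grp$summary, paths("diversity_groups.tsv"))
  })

  # --- structure -------------------------------------------------------------
  run_stage("structure", c("q_matrix.tsv", "delta_k.tsv", "assignments.tsv"),
            function() {
    sc <- config$structure %||% list()
    if (!is.null(sc$q_matrix)) {
      Q <- read_q_matrix(sc$q_matrix)
      if (!is.null(sc$lnpd)) {
        ks <- delta_k(read_lnpd_table(sc$lnpd))
        readr::write_tsv(tidy(ks), paths("delta_k.tsv"))
      } else {
        readr::write_tsv(tibble::tibble(), paths("delta_k.tsv"))
      }
    } else {
      mk <- select_structure_markers(panel, sc$min_spacing_cM %||% 20)
      sub <- subset_panel(panel, markers = mk)
      k_range <- sc$k_range %||% c(1L, 6L)
      n_rep <- sc$n_replicates %||% 3L
      runs <- purrr::map_dfr(seq(k_range[1], k_range[2]), function(k) {
        purrr::map_dfr(seq_len(n_rep), function(r) {
          em <- estimate_Q_em(sub, k,
                              seed = sub_seed(config$seed, 100L * k + r),
                              n_init = 1L)
          tibble::tibble(k = k, replicate = r, lnpd = em$loglik)
        })
      })
      ks <- delta_k(runs[, c("k", "lnpd")])
      readr::write_tsv(tidy(ks), paths("delta_k.tsv"))
      em <- estimate_Q_em(sub, attr(ks, "chosen_k"),
                          seed = sub_seed(config$seed, 7L))
      Q <- em$Q
    }
    write_matrix_tsv(Q, paths("q_matrix.tsv"))
    readr::write_tsv(assign_subpopulations(Q), paths("assignments.tsv"))
  })

  # --- kinship ---------------------------------------------------------------
  run_stage("kinship", "kinship.tsv", function() {
    write_matrix_tsv(loiselle_kinship(panel), paths("kinship.tsv"))
  })

  # --- LD --------------------------------------------------------------------
  run_stage("ld", c("ld_pairs.tsv", "ld_summary.tsv", "ld_decay.json"),
            function() {
    lc <- config$ld %||% list()
    pairs <- ld_pairs(panel, rare_threshold = lc$rare_threshold %||% 0.05,
                      n_perm = lc$n_perm %||% 200L,
                      seed = sub_seed(config$seed, 11L))
    readr::write_tsv(pairs, paths("ld_pairs.tsv"))
    readr::write_tsv(ld_summary(pairs, alpha = lc$alpha %||% 0.01),
                     paths("ld_summary.tsv"))
    bg <- background_ld(pairs)
    fit <- tryCatch(
      fit_decay(pairs, thresholds = c(background = bg, r2_0.1 = 0.1,
                                      r2_0.2 = 0.2),
                sig_alpha = lc$alpha %||% 0.01),
      error = function(e) NULL)
    jsonlite::write_json(list(
      background_r2 = bg,
      intercept = if (!is.null(fit)) fit$a else NA,
      slope = if (!is.null(fit)) fit$b else NA,
      crossings = if (!is.null(fit)) fit$crossings else list()
    ), paths("ld_decay.json"), auto_unbox = TRUE, digits = NA)
  })

  # --- phenotype statistics --------------------------------------------------
  run_stage("pheno", c("trait_summary.tsv", "variance_components.tsv",
                       "trait_correlations.tsv"),
            function() {
    traits <- unique(pheno$trait)
    envs <- unique(pheno$environment_id)
    summ <- purrr::map_dfr(traits, function(tr) {
      dplyr::bind_rows(
        purrr::map_dfr(envs, function(e) trait_summary(pheno, tr, e)),
        trait_summary(pheno, tr)
      )
    })
    readr::write_tsv(summ, paths("trait_summary.tsv"))
    vc <- purrr::map_dfr(traits, function(tr) {
      glance(suppressWarnings(anova_components(pheno, tr)))
    })
    readr::write_tsv(vc, paths("variance_components.tsv"))
    readr::write_tsv(trait_correlations(pheno), paths("trait_correlations.tsv"))
  })

  # --- association scan ------------------------------------------------------
  run_stage("assoc", c("association_scan.tsv", "association_table.tsv",
                       "association_summary.tsv"),
            function() {
    ac <- config$assoc %||% list()
    for (dep in c("q_matrix.tsv", "kinship.tsv")) {
      if (!file.exists(paths(dep))) {
        abort(paste0("stage 'assoc' is missing upstream output '", dep,
                     "' (run the structure/kinship stages first)"))
      }
    }
    Q <- structure_covariates(read_matrix_tsv(paths("q_matrix.tsv")))
    K <- read_matrix_tsv(paths("kinship.tsv"))
    records <- association_scan(
      panel, pheno, Q = Q, K = K,
      alpha = ac$alpha %||% 0.05, env_alpha = ac$env_alpha %||% 0.01,
      min_env = ac$min_env %||% 2L,
      rare_policy = ac$rare_policy %||% "pool")
    readr::write_tsv(records, paths("association_scan.tsv"))
    summ <- association_summary(records, m = ncol(panel$calls),
                                alpha = ac$alpha %||% 0.05,
                                env_alpha = ac$env_alpha %||% 0.01,
                                min_env = ac$min_env %||% 2L)
    readr::write_tsv(summ$associations, paths("association_table.tsv"))
    readr::write_tsv(summ$summary, paths("association_summary.tsv"))
  })

  # --- allele mining ---------------------------------------------------------
  run_stage("alleles", c("allele_effects.tsv", "transmission.tsv"),
            function() {
    al <- config$alleles %||% list()
    assoc_path <- paths("association_table.tsv")
    if (!file.exists(assoc_path)) {
      abort("allele mining needs the 'assoc' stage outputs")
    }
    assoc <- readr::read_tsv(assoc_path, show_col_types = FALSE,
                             progress = FALSE)
    pick <- if (isTRUE(al$include_unstable)) assoc
            else dplyr::filter(assoc, .data$stable)
    lm_across <- suppressWarnings(line_means(pheno, "across_environments"))
    objectives <- unlist(al$objectives) %||% DEFAULT_OBJECTIVES
    if (nrow(pick) == 0L) {
      readr::write_tsv(tibble::tibble(), paths("allele_effects.tsv"))
      readr::write_tsv(tibble::tibble(), paths("transmission.tsv"))
      return(invisible(NULL))
    }
    eff <- allele_effects(lm_across, panel, pick[, c("marker_id", "trait")],
                          objectives = objectives,
                          min_carriers = al$min_carriers %||% 0L)
    readr::write_tsv(eff, paths("allele_effects.tsv"))
    fav <- dplyr::filter(eff, .data$favorable)
    if (nrow(fav) > 0L && !is.null(panel$meta)) {
      tt <- transmission_table(
        panel, dplyr::distinct(fav[, c("marker_id", "allele")]),
        high_freq_threshold = al$high_freq_threshold %||% 0.8)
      readr::write_tsv(tt, paths("transmission.tsv"))
    } else {
      readr::write_tsv(tibble::tibble(), paths("transmission.tsv"))
    }
  })

  manifest$config <- config
  jsonlite::write_json(manifest, paths("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
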