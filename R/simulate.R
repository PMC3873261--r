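# ---- synthetic germplasm panel generator ------------------------------------

#' Default trait specification
#'
#' Seven lint-yield traits with grand means, line-mean coefficients of
#' variation and broad-sense heritabilities typical of a multi-environment
#' Upland cotton cultivar trial (three environments, two replicates). The
#' variance components are derived from the targets: with line-mean variance
#' \eqn{V_M} and heritability \eqn{h^2}, \eqn{\sigma^2_G = h^2 V_M} and the
#' remaining entry-mean variance is split evenly between the G-by-E and
#' residual contributions (\eqn{\sigma^2_{GE} = 1.5 (1-h^2) V_M},
#' \eqn{\sigma^2_e = 3 (1-h^2) V_M}).
#'
#' A shared latent "yield factor" couples the polygenic effects of the
#' traits: each trait's polygenic value mixes the shared factor with
#' trait-specific effects according to `yield_loading` (yield and its
#' primary components load strongly and positively, seed index negatively),
#' reproducing the characteristic sign pattern of lint-yield trait
#' correlations.
#'
#' @return A tibble with one row per trait: `trait`, `grand_mean`, `cv_pct`,
#'   `h2`, `yield_loading`, `sigma2_G`, `sigma2_GE`, `sigma2_e`, `n_env`,
#'   `n_rep`.
#' @export
default_trait_spec <- function() {
  spec <- tibble::tribble(
    ~trait, ~grand_mean, ~cv_pct, ~h2, ~yield_loading,
    "LY", 22.57, 29.09, 0.691, 0.90,
    "SY", 62.68, 23.19, 0.550, 0.85,
    "BN", 17.96, 19.36, 0.509, 0.70,
    "BW", 4.76, 9.11, 0.610, 0.30,
    "LP", 35.98, 9.33, 0.758, 0.50,
    "LI", 6.15, 12.48, 0.711, 0.50,
    "SI", 10.96, 9.02, 0.611, -0.30
  )
  spec |>
    dplyr::mutate(
      v_m = (.data$cv_pct / 100 * .data$grand_mean)^2,
      sigma2_G = .data$h2 * .data$v_m,
      sigma2_GE = 1.5 * (1 - .data$h2) * .data$v_m,
      sigma2_e = 3 * (1 - .data$h2) * .data$v_m,
      n_env = 3L, n_rep = 2L
    ) |>
    dplyr::select(-"v_m")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic panel generator. The defaults emulate
#' a Chinese Upland cotton association panel: ~350 homozygous lines, 145
#' multi-allelic loci (2-9 alleles, mostly 2-3) spread over 26 chromosomes
#' at roughly one marker per 10 cM, two admixed subpopulations at moderate
#' divergence, weak pairwise kinship, linkage disequilibrium decaying over a
#' few cM, and seven correlated traits scored in 3 environments x 2
#' replicates with heritabilities between ~0.27 and ~0.76.
#'
#' @param n_accessions,n_loci,n_chromosomes,chrom_length_cM Panel geometry.
#' @param alleles_per_locus_range Inclusive allele-count range, within 2-9.
#' @param n_subpops Number of ancestral subpopulations.
#' @param divergence_Fst Balding-Nichols divergence of subpopulation allele
#'   frequencies from the common ancestral frequencies.
#' @param admixture_alpha Dirichlet concentration of per-line admixture
#'   proportions (small = near-pure lines).
#' @param generations_of_mating Generations of recombination applied when
#'   building founder-haplotype mosaics (controls LD decay; Haldane map
#'   function).
#' @param n_founder_haplotypes Founder-pool size per subpopulation.
#' @param n_ancestral_haplotypes Number of panel-wide deep ancestral
#'   haplotypes from which every founder is recombined. The narrow
#'   ancestral base is the source of linkage disequilibrium -- tightly
#'   linked loci ride the same ancestral segment -- and mimics breeding
#'   programs descended from a handful of founder parents. Subpopulations
#'   differ in their ancestor-usage weights (Dirichlet drift scaled by
#'   `divergence_Fst`), not in which ancestors exist, so unlinked loci pick
#'   up only structure-driven association.
#' @param founder_generations Generations of recombination separating the
#'   founder pool from the ancestral haplotypes (controls how far LD
#'   extends within the pool).
#' @param missing_rate Uniform genotype missingness.
#' @param qtl_spec Optional tibble `(marker_id, trait, allele, effect)` of
#'   per-allele additive effects in trait units; `NULL` installs a default
#'   set of shared QTLs (see [simulate_panel()]).
#' @param trait_spec Trait table as in [default_trait_spec()].
#' @param era_assignment Named proportions per era group (must include CK).
#' @param seed Integer seed; all randomness flows from it through
#'   per-stage sub-streams.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 350L, n_loci = 145L,
                       n_chromosomes = 26L, chrom_length_cM = 60,
                       alleles_per_locus_range = c(2L, 9L),
                       n_subpops = 2L, divergence_Fst = 0.15,
                       admixture_alpha = 0.2, generations_of_mating = 10L,
                       n_founder_haplotypes = 16L,
                       n_ancestral_haplotypes = 8L,
                       founder_generations = 5L, missing_rate = 0.03,
                       qtl_spec = NULL, trait_spec = default_trait_spec(),
                       era_assignment = c(CK = 6, I = 26, II = 26, III = 39,
                                          IV = 83, V = 125, VI = 51) / 356,
                       seed = 1L) {
  assert_proportion(divergence_Fst, "divergence_Fst")
  assert_proportion(missing_rate, "missing_rate")
  if (alleles_per_locus_range[1] < 2L || alleles_per_locus_range[2] > 9L) {
    abort("alleles_per_locus_range must lie within [2, 9]")
  }
  if (abs(sum(era_assignment) - 1) > 1e-6) {
    abort("era_assignment proportions must sum to 1")
  }
  if (!"CK" %in% names(era_assignment)) abort("era_assignment must include CK")
  if (is.null(seed)) abort("a seed is required; implicit seeding is refused")
  trait_spec <- tibble::as_tibble(trait_spec)
  bad_var <- trait_spec$sigma2_G < 0 | trait_spec$sigma2_GE < 0 |
    trait_spec$sigma2_e < 0
  if (any(bad_var)) abort("negative variance target in trait_spec")
  structure(list(
    n_accessions = as.integer(n_accessions), n_loci = as.integer(n_loci),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = chrom_length_cM,
    alleles_per_locus_range = as.integer(alleles_per_locus_range),
    n_subpops = as.integer(n_subpops), divergence_Fst = divergence_Fst,
    admixture_alpha = admixture_alpha,
    generations_of_mating = as.integer(generations_of_mating),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    founder_generations = as.integer(founder_generations),
    missing_rate = missing_rate, qtl_spec = qtl_spec,
    trait_spec = trait_spec, era_assignment = era_assignment,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a structured germplasm panel
#'
#' Generates homozygous lines by (a) drawing per-subpopulation allele
#' frequencies around common ancestral frequencies under a Balding-Nichols
#' divergence model parameterised by `divergence_Fst`, (b) drawing per-line
#' admixture proportions from a Dirichlet(`admixture_alpha`), and (c)
#' building each chromosome as a mosaic of founder haplotypes with
#' recombination accumulated over `generations_of_mating` generations at
#' genetic-map distances (Haldane). Lines are represented by a single
#' haplotype: doubling to homozygosity is implicit. Phenotypes are grand
#' mean + environment offset + QTL allele effects + a polygenic line effect
#' scaled to the genetic variance target + G-by-E deviation + replicate
#' error. Missing genotype calls are masked uniformly at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A `sim_panel` list: `panel` ([genotype_panel()] with metadata),
#'   `pheno` (long phenotype tibble), `meta`, and `truth` (true memberships
#'   and admixture, subpopulation allele frequencies, the QTL effect map and
#'   realized per-trait variance components and heritability).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  # --- map -------------------------------------------------------------------
  chrom_of <- rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_loci)
  chrom_of <- sort(chrom_of)
  map <- tibble::tibble(
    marker_id = sprintf("M%03d", seq_len(cfg$n_loci)),
    chromosome = sprintf("C%02d", chrom_of)
  ) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(position_cM = (dplyr::row_number() - 1L) *
                    cfg$chrom_length_cM / max(1L, dplyr::n() - 1L)) |>
    dplyr::ungroup()

  # --- ancestral and subpopulation allele frequencies ------------------------
  geno <- with_seed(sub_seed(cfg$seed, 1L), {
    n_alleles <- sample(seq(cfg$alleles_per_locus_range[1],
                            cfg$alleles_per_locus_range[2]),
                        cfg$n_loci, replace = TRUE,
                        prob = c(0.45, 0.35, 0.09, 0.05, 0.03, 0.015, 0.01,
                                 0.005)[seq_len(diff(cfg$alleles_per_locus_range) + 1L)])
    anc_freqs <- lapply(n_alleles, function(a) drop(rdirichlet(1, rep(0.8, a))))
    fst <- max(cfg$divergence_Fst, 1e-4)
    A <- cfg$n_ancestral_haplotypes
    # panel-wide ancestral haplotypes (iid draws from the ancestral
    # frequencies); linked loci become correlated because lines inherit
    # whole ancestral segments
    ancestors <- vapply(anc_freqs, function(p) {
      sample.int(length(p), A, replace = TRUE, prob = p)
    }, integer(A))
    # subpopulations differ only in how often they use each ancestor:
    # Balding-Nichols-style Dirichlet drift on the usage weights
    usage <- lapply(seq_len(cfg$n_subpops), function(s) {
      drop(rdirichlet(1, rep((1 - fst) / fst / A, A)))
    })
    subpop_freqs <- lapply(usage, function(w) {
      lapply(seq_len(cfg$n_loci), function(l) {
        vapply(seq_along(anc_freqs[[l]]), function(a) {
          sum(w[ancestors[, l] == a])
        }, numeric(1))
      })
    })
    # founder pool per subpopulation: recombinant mosaics of the ancestors
    gaps_f <- c(Inf, diff(map$position_cM))
    gaps_f[c(TRUE, map$chromosome[-1] != map$chromosome[-cfg$n_loci])] <- Inf
    p_switch_f <- 1 - exp(-cfg$founder_generations * gaps_f / 100)
    founders <- lapply(usage, function(w) {
      t(vapply(seq_len(cfg$n_founder_haplotypes), function(f) {
        hap <- integer(cfg$n_loci)
        a <- 1L
        for (l in seq_len(cfg$n_loci)) {
          if (runif(1) < p_switch_f[l]) {
            a <- sample.int(A, 1L, prob = w)
          }
          hap[l] <- ancestors[a, l]
        }
        hap
      }, integer(cfg$n_loci)))
    })
    Q_true <- rdirichlet(cfg$n_accessions,
                         rep(cfg$admixture_alpha, cfg$n_subpops))
    # founder-mosaic walk along each chromosome (Haldane, g generations)
    calls <- matrix(NA_integer_, cfg$n_accessions, cfg$n_loci)
    gaps <- c(Inf, diff(map$position_cM))
    gaps[c(TRUE, map$chromosome[-1] != map$chromosome[-cfg$n_loci])] <- Inf
    p_switch <- 1 - exp(-cfg$generations_of_mating * gaps / 100)
    for (i in seq_len(cfg$n_accessions)) {
      sub <- 0L; fou <- 0L
      for (l in seq_len(cfg$n_loci)) {
        if (runif(1) < p_switch[l]) {
          sub <- sample.int(cfg$n_subpops, 1L, prob = Q_true[i, ])
          fou <- sample.int(cfg$n_founder_haplotypes, 1L)
        }
        calls[i, l] <- founders[[sub]][fou, l]
      }
    }
    list(calls = calls, Q_true = Q_true, subpop_freqs = subpop_freqs,
         n_alleles = n_alleles)
  })
  calls <- geno$calls
  dimnames(calls) <- list(sprintf("A%03d", seq_len(cfg$n_accessions)),
                          map$marker_id)
  true_subpop <- max.col(geno$Q_true, ties.method = "first")

  # --- metadata --------------------------------------------------------------
  meta <- with_seed(sub_seed(cfg$seed, 4L), {
    counts <- round(cfg$era_assignment * cfg$n_accessions)
    counts[1] <- max(counts[1], 1L)
    while (sum(counts) > cfg$n_accessions) {
      j <- which.max(counts[-1]) + 1L
      counts[j] <- counts[j] - 1L
    }
    while (sum(counts) < cfg$n_accessions) {
      j <- which.max(cfg$era_assignment)
      counts[j] <- counts[j] + 1L
    }
    era <- sample(rep(names(counts), counts))
    regions <- c("YellowRiver", "YangtzeRiver", "NorthNW")
    region_probs <- list(c(0.55, 0.05, 0.40), c(0.48, 0.44, 0.08))
    region <- vapply(seq_len(cfg$n_accessions), function(i) {
      pr <- region_probs[[min(true_subpop[i], 2L)]]
      sample(regions, 1L, prob = pr)
    }, character(1))
    tibble::tibble(accession_id = rownames(calls), era_group = era,
                   region = region, is_founder = era == "CK")
  })

  # --- phenotypes ------------------------------------------------------------
  qtl <- cfg$qtl_spec %||% default_qtl_spec(map, cfg$trait_spec, calls)
  missing_qtl <- setdiff(unique(qtl$marker_id), map$marker_id)
  if (length(missing_qtl) > 0) {
    abort(paste0("QTL marker(s) not in map: ",
                 paste(missing_qtl, collapse = ", ")))
  }
  ph <- with_seed(sub_seed(cfg$seed, 2L), {
    records <- list(); truth_rows <- list()
    # shared polygenic "yield factor": per-locus allele effects drawn once,
    # mixed into each trait according to its loading
    shared_raw <- rep(0, cfg$n_accessions)
    for (l in seq_len(ncol(calls))) {
      eff <- rnorm(geno$n_alleles[l], 0, 1)
      shared_raw <- shared_raw + eff[calls[, l]]
    }
    shared_raw <- (shared_raw - mean(shared_raw)) /
      max(sd(shared_raw), 1e-12)
    for (ti in seq_len(nrow(cfg$trait_spec))) {
      ts <- cfg$trait_spec[ti, ]
      loading <- if ("yield_loading" %in% names(ts)) ts$yield_loading else 0
      qtl_t <- dplyr::filter(qtl, .data$trait == ts$trait)
      qtl_val <- rep(0, cfg$n_accessions)
      for (r in seq_len(nrow(qtl_t))) {
        hit <- !is.na(calls[, qtl_t$marker_id[r]]) &
          calls[, qtl_t$marker_id[r]] == qtl_t$allele[r]
        qtl_val <- qtl_val + hit * qtl_t$effect[r]
      }
      own_raw <- rep(0, cfg$n_accessions)
      for (l in seq_len(ncol(calls))) {
        eff <- rnorm(geno$n_alleles[l], 0, 1)
        own_raw <- own_raw + eff[calls[, l]]
      }
      own_raw <- (own_raw - mean(own_raw)) / max(sd(own_raw), 1e-12)
      poly_raw <- loading * shared_raw +
        sqrt(max(1 - loading^2, 0)) * own_raw
      var_qtl <- var(qtl_val)
      target_poly <- max(ts$sigma2_G - var_qtl, 0.05 * ts$sigma2_G)
      poly <- poly_raw * sqrt(target_poly) / max(sd(poly_raw), 1e-12)
      genetic <- qtl_val + poly
      v_m <- ts$sigma2_G + ts$sigma2_GE / ts$n_env +
        ts$sigma2_e / (ts$n_env * ts$n_rep)
      env_offsets <- if (ts$n_env == 1L) 0 else
        seq(-0.6, 0.6, length.out = ts$n_env) * sqrt(v_m)
      ge <- matrix(rnorm(cfg$n_accessions * ts$n_env, 0, sqrt(ts$sigma2_GE)),
                   cfg$n_accessions, ts$n_env)
      for (e in seq_len(ts$n_env)) {
        for (rp in seq_len(ts$n_rep)) {
          err <- rnorm(cfg$n_accessions, 0, sqrt(ts$sigma2_e))
          records[[length(records) + 1L]] <- tibble::tibble(
            accession_id = rownames(calls),
            environment_id = sprintf("E%d", e),
            replicate_id = sprintf("R%d", rp),
            trait = ts$trait,
            value = ts$grand_mean + env_offsets[e] + genetic + ge[, e] + err
          )
        }
      }
      realized_ge <- mean(apply(ge, 2, var))
      truth_rows[[ti]] <- tibble::tibble(
        trait = ts$trait,
        var_G_realized = var(genetic),
        var_GE_realized = realized_ge,
        var_e_target = ts$sigma2_e,
        h2_target = ts$h2 %||% NA_real_,
        h2_realized = var(genetic) /
          (var(genetic) + realized_ge / ts$n_env +
             ts$sigma2_e / (ts$n_env * ts$n_rep))
      )
    }
    list(pheno = dplyr::bind_rows(records),
         trait_truth = dplyr::bind_rows(truth_rows))
  })

  # --- missingness -----------------------------------------------------------
  calls_masked <- with_seed(sub_seed(cfg$seed, 3L), {
    mask <- matrix(runif(length(calls)) < cfg$missing_rate, nrow(calls))
    out <- calls
    out[mask] <- NA_integer_
    out
  })

  panel <- genotype_panel(calls_masked, map, meta)
  truth <- list(
    subpop = setNames(true_subpop, rownames(calls)),
    Q_true = geno$Q_true,
    subpop_freqs = geno$subpop_freqs,
    qtl = qtl,
    trait_truth = ph$trait_truth,
    calls_unmasked = calls,
    config = cfg
  )
  structure(list(panel = panel, pheno = ph$pheno, meta = meta, truth = truth),
            class = "sim_panel")
}

# default QTL map: a few loci spread across the genome, shared between
# correlated traits; effects are half a genetic standard deviation per trait
default_qtl_spec <- function(map, trait_spec, calls) {
  n_loci <- nrow(map)
  pick <- map$marker_id[round(seq(0.1, 0.9, length.out = 6L) * n_loci)]
  sd_g <- setNames(sqrt(trait_spec$sigma2_G), trait_spec$trait)
  present <- function(m) {
    tab <- table(calls[, m])
    as.integer(names(tab)[which.max(tab)]) # the major allele carries effect
  }
  entries <- list(
    list(m = pick[1], traits = c("LY", "SY")),
    list(m = pick[2], traits = c("LY", "SY", "BN")),
    list(m = pick[3], traits = c("LP", "LI")),
    list(m = pick[4], traits = "BW"),
    list(m = pick[5], traits = "LP"),
    list(m = pick[6], traits = "SI")
  )
  out <- purrr::map_dfr(entries, function(e) {
    keep <- intersect(e$traits, names(sd_g))
    if (length(keep) == 0L) return(NULL)
    tibble::tibble(marker_id = e$m, trait = keep,
                   allele = present(e$m),
                   effect = 0.5 * unname(sd_g[keep]))
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(marker_id = character(), trait = character(),
                          allele = integer(), effect = double())
  }
  out
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel>\n")
  print(x$panel)
  cat("  phenotypes:", nrow(x$pheno), "records,",
      length(unique(x$pheno$trait)), "traits\n")
  invisible(x)
}

#' Compare a simulated panel against its configuration targets
#'
#' Report-only realism check: realized divergence (Fst) between the true
#' subpopulations, mean alleles per locus, rare-allele fraction, LD
#' half-decay distance among linked pairs, and realized broad-sense
#' heritability per trait (from the multi-environment ANOVA), each next to
#' its configured target.
#'
#' @param sim A [simulate_panel()] result.
#' @return A tibble `(metric, value, target)`.
#' @export
verify_realism <- function(sim) {
  stopifnot(inherits(sim, "sim_panel"))
  cfg <- sim$truth$config
  calls <- sim$truth$calls_unmasked
  subpop <- sim$truth$subpop

  # realized Fst: 1 - mean(Hs)/Ht averaged over loci
  fst_per_locus <- vapply(seq_len(ncol(calls)), function(l) {
    x <- calls[, l]
    ht <- gene_diversity(as.numeric(table(x)) / length(x))
    if (ht == 0) return(NA_real_)
    hs <- vapply(unique(subpop), function(s) {
      xs <- x[subpop == s]
      gene_diversity(as.numeric(table(xs)) / length(xs))
    }, numeric(1))
    1 - mean(hs) / ht
  }, numeric(1))

  div <- locus_diversity(sim$panel)
  n_alleles_total <- sum(div$n_alleles)
  rare_frac <- sum(lengths(div$rare_alleles)) / n_alleles_total

  # LD half-decay from an unfiltered log fit on linked pairs
  mk <- sim$panel$map
  linked <- dplyr::inner_join(mk, mk, by = "chromosome",
                              suffix = c("_a", "_b"),
                              relationship = "many-to-many") |>
    dplyr::filter(.data$marker_id_a < .data$marker_id_b) |>
    dplyr::mutate(distance_cM = abs(.data$position_cM_a - .data$position_cM_b)) |>
    dplyr::filter(.data$distance_cM > 0)
  r2s <- purrr::pmap_dbl(linked[, c("marker_id_a", "marker_id_b")],
                         function(marker_id_a, marker_id_b) {
    x <- calls[, marker_id_a]; y <- calls[, marker_id_b]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
    weighted_r2(x, y)
  })
  ok <- !is.na(r2s)
  half_decay <- NA_real_
  if (sum(ok) >= 3L) {
    fit <- lm(r2 ~ log(d), data = tibble::tibble(r2 = r2s[ok],
                                                 d = linked$distance_cM[ok]))
    a <- coef(fit)[1]; b <- coef(fit)[2]
    r2_near <- a + b * log(min(linked$distance_cM[ok]))
    if (b < 0) half_decay <- unname(exp((r2_near / 2 - a) / b))
  }

  h2_rows <- purrr::map_dfr(unique(sim$pheno$trait), function(tr) {
    vc <- suppressWarnings(anova_components(sim$pheno, tr))
    tibble::tibble(metric = paste0("h2_realized_", tr),
                   value = heritability(vc),
                   target = cfg$trait_spec$h2[cfg$trait_spec$trait == tr])
  })

  dplyr::bind_rows(
    tibble::tibble(metric = "fst_realized",
                   value = mean(fst_per_locus, na.rm = TRUE),
                   target = cfg$divergence_Fst),
    tibble::tibble(metric = "mean_alleles_per_locus",
                   value = mean(div$n_alleles),
                   target = mean(cfg$alleles_per_locus_range)),
    tibble::tibble(metric = "min_alleles_per_locus",
                   value = min(div$n_alleles),
                   target = cfg$alleles_per_locus_range[1]),
    tibble::tibble(metric = "max_alleles_per_locus",
                   value = max(div$n_alleles),
                   target = cfg$alleles_per_locus_range[2]),
    tibble::tibble(metric = "rare_allele_fraction",
                   value = rare_frac, target = NA_real_),
    tibble::tibble(metric = "ld_half_decay_cM",
                   value = half_decay, target = NA_real_),
    h2_rows
  )
}
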