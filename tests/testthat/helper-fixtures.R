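# small deterministic fixtures used across test files

# 6 homozygous lines x 4 markers on 2 chromosomes, no missing data
tiny_panel <- function() {
  calls <- matrix(
    c(1L, 1L, 2L, 2L, 1L, 2L,   # M1
      1L, 2L, 1L, 2L, 2L, 1L,   # M2
      1L, 1L, 1L, 2L, 3L, 3L,   # M3
      2L, 2L, 2L, 2L, 1L, 1L),  # M4
    nrow = 6,
    dimnames = list(paste0("A", 1:6), paste0("M", 1:4))
  )
  map <- tibble::tibble(
    marker_id = paste0("M", 1:4),
    chromosome = c("C1", "C1", "C2", "C2"),
    position_cM = c(0, 12, 0, 25)
  )
  genotype_panel(calls, map)
}

tiny_meta <- function() {
  tibble::tibble(
    accession_id = paste0("A", 1:6),
    era_group = c("CK", "I", "I", "II", "II", "II"),
    region = "R1",
    is_founder = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

# balanced two-environment, two-replicate phenotype table for one trait
balanced_pheno <- function(accessions = paste0("A", 1:6), trait = "LY",
                           envs = c("E1", "E2"), reps = c("R1", "R2"),
                           values = NULL, seed = 1) {
  grid <- expand.grid(accession_id = accessions, environment_id = envs,
                      replicate_id = reps, trait = trait,
                      stringsAsFactors = FALSE)
  if (is.null(values)) {
    values <- withr::with_seed(seed, rnorm(nrow(grid), 20, 3))
  }
  tibble::tibble(grid, value = values)
}

# simulate phenotypes from the two-factor model with known components
sim_anova_data <- function(n_geno, n_env, n_rep, s2_g, s2_ge, s2_e,
                           seed = 1, mu = 10) {
  withr::with_seed(seed, {
    g <- rnorm(n_geno, 0, sqrt(s2_g))
    ge <- matrix(rnorm(n_geno * n_env, 0, sqrt(s2_ge)), n_geno, n_env)
    env_eff <- rnorm(n_env, 0, 1)
    recs <- list()
    for (e in seq_len(n_env)) for (r in seq_len(n_rep)) {
      recs[[length(recs) + 1L]] <- tibble::tibble(
        accession_id = sprintf("G%03d", seq_len(n_geno)),
        environment_id = paste0("E", e),
        replicate_id = paste0("R", r),
        trait = "T1",
        value = mu + env_eff[e] + g + ge[, e] +
          rnorm(n_geno, 0, sqrt(s2_e))
      )
    }
    dplyr::bind_rows(recs)
  })
}

# draw a random homozygous panel with independent loci (no linkage structure)
random_panel <- function(n = 30, n_loci = 5, n_alleles = 3, seed = 1,
                         two_chrom = TRUE) {
  withr::with_seed(seed, {
    calls <- matrix(sample.int(n_alleles, n * n_loci, replace = TRUE),
                    nrow = n,
                    dimnames = list(sprintf("A%03d", seq_len(n)),
                                    sprintf("M%02d", seq_len(n_loci))))
    chrom <- if (two_chrom) rep(c("C1", "C2"), length.out = n_loci) else "C1"
    map <- tibble::tibble(marker_id = colnames(calls),
                          chromosome = sort(chrom),
                          position_cM = seq(0, 50, length.out = n_loci))
    genotype_panel(calls, map)
  })
}

# the bundled worked-example association-scan table, in long form
example_scan_records <- function() {
  path <- system.file("extdata", "cotton_scan_example.tsv",
                      package = "alleleminer")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    tidyr::pivot_longer(dplyr::starts_with("nlp_"),
                        names_to = "environment", names_prefix = "nlp_",
                        values_to = "neg_log10_p") |>
    dplyr::filter(!is.na(neg_log10_p))
}

example_frequency_table <- function() {
  readr::read_tsv(system.file("extdata", "cotton_allele_frequencies.tsv",
                              package = "alleleminer"),
                  show_col_types = FALSE, progress = FALSE)
}
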