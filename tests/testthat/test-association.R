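# one-way fixed-effects ANOVA oracle for a categorical marker
ols_anova_p <- function(y, x) {
  full <- lm(y ~ factor(x))
  null <- lm(y ~ 1)
  a <- anova(null, full)
  a$`Pr(>F)`[2]
}

test_that("the Bonferroni threshold matches its closed form", {
  expect_equal(round(bonferroni_threshold(145, 0.05), 2), 3.46)
  expect_equal(bonferroni_threshold(145, 0.05), -log10(0.05 / 145))
  expect_equal(round(bonferroni_threshold(1, 0.05), 4), 1.3010)
  expect_equal(round(bonferroni_threshold(20, 0.05), 4), 2.6021)
  expect_error(bonferroni_threshold(0), ">= 1")
  expect_error(bonferroni_threshold(10, 1.2), "alpha")
})

test_that("with K = I and no Q the scan equals one-way ANOVA", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 40
      panel <- random_panel(n = n, n_loci = 4, n_alleles = 3,
                            seed = 100 + rep)
      y <- setNames(rnorm(n, 10, 2), rownames(panel$calls))
      K <- diag(n); dimnames(K) <- list(names(y), names(y))
      fit <- fit_null_mlm(y, Q = NULL, K = K)
      sc <- suppressMessages(marker_scan(fit, panel, rare_policy = "none"))
      for (i in seq_len(nrow(sc))) {
        m <- sc$marker_id[i]
        expect_equal(sc$p_value[i], ols_anova_p(y, panel$calls[, m]),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("flat variance profiles fall back to the OLS boundary", {
  withr::with_seed(32, {
    n <- 30
    y <- setNames(rnorm(n), sprintf("A%03d", 1:n))
    K <- diag(n); dimnames(K) <- list(names(y), names(y))
    fit <- fit_null_mlm(y, K = K)
    expect_equal(fit$sigma2_g, 0)
    expect_equal(fit$sigma2_e, var(y) * (n - 1) / (n - 1), tolerance = 1e-6)
  })
})

test_that("REML recovers a moderate heritability on a known kinship", {
  sim <- simulate_panel(sim_config(n_accessions = 200L, n_loci = 60L,
                                   n_chromosomes = 10L, seed = 41))
  K <- loiselle_kinship(sim$panel)
  Kb <- as.matrix(unclass(K))
  ev <- eigen((Kb + t(Kb)) / 2, symmetric = TRUE)
  Kpsd <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  dimnames(Kpsd) <- dimnames(Kb)
  L <- chol(Kpsd + diag(1e-6, nrow(Kpsd)))
  h2 <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      u <- drop(t(L) %*% rnorm(nrow(Kpsd)))
      y <- u + rnorm(nrow(Kpsd), 0, sqrt(mean(diag(Kpsd))))
    })
    names(y) <- rownames(Kpsd)
    fit <- fit_null_mlm(y, K = Kpsd)
    fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.15)
})

test_that("pure-noise phenotypes drive the genetic variance to the boundary", {
  # under the null the REML variance ratio has the classic boundary mixture:
  # a point mass at zero plus small positive estimates
  sim <- simulate_panel(sim_config(n_accessions = 120L, n_loci = 50L,
                                   n_chromosomes = 10L, seed = 42))
  K <- loiselle_kinship(sim$panel)
  ratios <- vapply(1:20, function(s) {
    y <- withr::with_seed(300 + s,
                          setNames(rnorm(nrow(K)), rownames(K)))
    fit <- fit_null_mlm(y, K = K)
    fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  }, numeric(1))
  expect_lt(median(ratios), 0.05)
  expect_gte(mean(ratios == 0), 0.25)
  expect_lt(mean(ratios), 0.15)
})

test_that("a causal marker of half a phenotypic SD is detected at Bonferroni", {
  m_tests <- 100
  thr <- bonferroni_threshold(m_tests, 0.05)
  hits <- vapply(1:10, function(s) {
    withr::with_seed(500 + s, {
      n <- 300
      x <- sample(1:2, n, replace = TRUE)
      y <- setNames(0.5 * (x == 2) + rnorm(n), sprintf("A%03d", 1:n))
      calls <- cbind(Mq = as.integer(x))
      rownames(calls) <- names(y)
      panel <- genotype_panel(calls,
                              tibble::tibble(marker_id = "Mq",
                                             chromosome = "C1",
                                             position_cM = 0))
      K <- diag(n); dimnames(K) <- list(names(y), names(y))
      fit <- fit_null_mlm(y, K = K)
      sc <- marker_scan(fit, panel)
      sc$neg_log10_p >= thr
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("p-values are invariant to affine rescaling of the phenotype", {
  sim <- simulate_panel(sim_config(n_accessions = 100L, n_loci = 30L,
                                   n_chromosomes = 6L, seed = 43))
  K <- loiselle_kinship(sim$panel)
  em <- estimate_Q_em(sim$panel, 2, seed = 1)
  lm_env <- line_means(sim$pheno, "per_environment")
  cell <- dplyr::filter(lm_env, trait == "LY", environment_id == "E1")
  y <- setNames(cell$value, cell$accession_id)
  Qc <- structure_covariates(em$Q)
  sc1 <- suppressMessages(
    marker_scan(fit_null_mlm(y, Qc, K), sim$panel))
  sc2 <- suppressMessages(
    marker_scan(fit_null_mlm(3 * y + 10, Qc, K), sim$panel))
  expect_equal(sc1$neg_log10_p, sc2$neg_log10_p, tolerance = 1e-6)
})

test_that("monomorphic and rare-collapsed markers are skipped", {
  n <- 30
  calls <- cbind(Mmono = rep(1L, n),
                 Mrare = c(rep(1L, n - 1), 2L))
  rownames(calls) <- sprintf("A%03d", 1:n)
  panel <- genotype_panel(calls,
                          tibble::tibble(marker_id = c("Mmono", "Mrare"),
                                         chromosome = "C1",
                                         position_cM = c(0, 1)))
  y <- withr::with_seed(44, setNames(rnorm(n), rownames(calls)))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  fit <- fit_null_mlm(y, K = K)
  # dropping the rare allele leaves both markers monomorphic
  expect_message(sc <- marker_scan(fit, panel, rare_policy = "drop"),
                 "monomorphic")
  expect_equal(nrow(sc), 0)
  # pooling keeps the rare class as "other", so the marker stays testable
  sc2 <- suppressMessages(marker_scan(fit, panel, rare_policy = "pool"))
  expect_equal(sc2$marker_id, "Mrare")
})

test_that("structure-confounded nulls inflate the naive scan but not Q+K", {
  res <- t(vapply(1:8, function(s) {
    sim <- simulate_panel(sim_config(
      n_accessions = 120L, n_loci = 60L, n_chromosomes = 10L,
      divergence_Fst = 0.15, admixture_alpha = 0.1, seed = 600 + s))
    subpop <- sim$truth$subpop
    y <- withr::with_seed(700 + s,
                          setNames(1.5 * (subpop == 1) +
                                     rnorm(length(subpop)),
                                   names(subpop)))
    K <- loiselle_kinship(sim$panel)
    Ident <- diag(length(y)); dimnames(Ident) <- list(names(y), names(y))
    em <- estimate_Q_em(sim$panel, 2, seed = 600 + s, n_init = 1)
    naive <- suppressMessages(
      marker_scan(fit_null_mlm(y, K = Ident), sim$panel))
    qk <- suppressMessages(
      marker_scan(fit_null_mlm(y, structure_covariates(em$Q), K),
                  sim$panel))
    c(naive = mean(naive$p_value <= 0.01), qk = mean(qk$p_value <= 0.01))
  }, numeric(2)))
  expect_gt(mean(res[, "naive"]), mean(res[, "qk"]))
})

test_that("stability flags require Bonferroni somewhere plus repeat detection", {
  recs <- tibble::tibble(
    marker_id = rep(c("m1", "m2", "m3"), each = 3),
    trait = "LY",
    environment = rep(c("E1", "E2", "E3"), 3),
    neg_log10_p = c(4.1, 2.5, 1.0,    # stable: Bonferroni in E1, detected twice
                    4.0, 1.2, 0.5,    # not stable: detected once
                    4.2, 4.4, 4.6)    # stable in all three
  )
  out <- stability_filter(recs, m = 145)
  m1 <- out[out$marker_id == "m1", ]
  expect_true(all(m1$stable))
  expect_equal(unique(m1$n_env_detected), 2L)
  expect_false(any(out$stable[out$marker_id == "m2"]))
  expect_equal(unique(out$n_env_detected[out$marker_id == "m3"]), 3L)
  summ <- association_summary(recs, m = 145)
  expect_equal(summ$summary$n_associations, 3L)
  expect_equal(summ$summary$n_stable, 2L)
})
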