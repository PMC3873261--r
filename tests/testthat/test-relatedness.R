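test_that("delta-k reproduces the hand-computed curvature statistic", {
  runs <- tibble::tibble(
    k = c(1, 1, 2, 2, 3, 3),
    lnpd = c(-100, -100, -90, -92, -88, -88)
  )
  ks <- delta_k(runs)
  expect_equal(ks$delta_k[ks$k == 2], 6 / sd(c(-90, -92)), tolerance = 1e-12)
  expect_equal(round(ks$delta_k[ks$k == 2], 4), 4.2426)
  expect_equal(attr(ks, "chosen_k"), 2L)
})

test_that("linear LnP(D) means give zero curvature everywhere", {
  runs <- tibble::tibble(
    k = rep(1:4, each = 2),
    lnpd = rep(c(-100, -90, -80, -70), each = 2) + rep(c(-0.5, 0.5), 4)
  )
  # every interior curvature is zero (a flat maximum, reported with a
  # tie warning and resolved toward the smaller k)
  expect_warning(ks <- delta_k(runs), "tie")
  expect_equal(ks$delta_k[!is.na(ks$delta_k)], c(0, 0))
  expect_equal(attr(ks, "chosen_k"), 2L)
})

test_that("delta-k input validation and tie-breaking behave as documented", {
  expect_error(delta_k(tibble::tibble(k = c(1, 2), lnpd = c(-1, -2))),
               "consecutive")
  runs_sd0 <- tibble::tibble(k = rep(1:3, each = 2),
                             lnpd = c(-10, -11, -9, -9, -8, -8.5))
  expect_error(delta_k(runs_sd0), "zero at k = 2")
  # a symmetric double peak ties: the smaller k wins, with a warning
  runs_tie <- tibble::tibble(
    k = rep(1:5, each = 2),
    lnpd = rep(c(-100, -80, -75, -70, -50), each = 2) + rep(c(-1, 1), 5)
  )
  expect_warning(ks <- delta_k(runs_tie), "tie")
  expect_equal(attr(ks, "chosen_k"), 2L)
  # invariance to a constant shift of every replicate
  shifted <- dplyr::mutate(runs_tie, lnpd = lnpd + 500)
  expect_equal(suppressWarnings(delta_k(shifted)$delta_k),
               suppressWarnings(delta_k(runs_tie)$delta_k))
})

test_that("Q-based assignment follows the strict majority rule", {
  Q <- rbind(A1 = c(0.8, 0.2), A2 = c(0.5, 0.5), A3 = c(0.3, 0.7))
  asg <- assign_subpopulations(Q)
  expect_equal(asg$subpop, c("P1", "ADMIXED", "P2"))
  expect_error(assign_subpopulations(rbind(c(0.6, 0.6))), "sum to 1")
})

test_that("the admixture EM has a closed form at k = 1 and monotone likelihood", {
  panel <- tiny_panel()
  em <- estimate_Q_em(panel, k = 1, seed = 1, n_init = 1)
  expect_true(all(em$Q == 1))
  oracle <- sum(vapply(colnames(panel$calls), function(m) {
    f <- allele_frequencies(panel, m)
    sum(log(f[as.character(panel$calls[, m])]))
  }, numeric(1)))
  expect_equal(em$loglik, oracle, tolerance = 1e-4)
  expect_true(all(diff(em$trace) >= -1e-8))

  em2 <- estimate_Q_em(panel, k = 2, seed = 1)
  expect_true(all(abs(rowSums(em2$Q) - 1) < 1e-8))
  expect_true(all(diff(em2$trace) >= -1e-8))
  expect_error(estimate_Q_em(panel, k = 10), "exceeds")
})

test_that("a monomorphic panel converges immediately", {
  calls <- matrix(1L, 5, 3, dimnames = list(paste0("A", 1:5),
                                            paste0("M", 1:3)))
  panel <- genotype_panel(calls, tibble::tibble(marker_id = paste0("M", 1:3),
                                                chromosome = "C1",
                                                position_cM = 0:2))
  em <- estimate_Q_em(panel, k = 2, seed = 1, n_init = 1)
  expect_lte(length(em$trace), 3L)
})

test_that("the EM recovers strong two-subpopulation structure", {
  hits <- vapply(1:3, function(s) {
    sim <- simulate_panel(sim_config(
      n_accessions = 120L, n_loci = 60L, n_chromosomes = 10L,
      divergence_Fst = 0.2, admixture_alpha = 0.05, seed = s))
    em <- estimate_Q_em(sim$panel, 2, seed = s)
    hard <- max.col(em$Q)
    tru <- sim$truth$subpop
    max(mean(hard == tru), mean(hard == 3 - tru))  # label-permutation safe
  }, numeric(1))
  expect_true(all(hits > 0.9))
})

test_that("Loiselle kinship matches hand arithmetic on a biallelic locus", {
  calls <- matrix(c(1L, 1L, 2L, 2L), 4, 1,
                  dimnames = list(paste0("A", 1:4), "M1"))
  panel <- genotype_panel(calls, tibble::tibble(marker_id = "M1",
                                                chromosome = "C1",
                                                position_cM = 0))
  Kraw <- loiselle_kinship(panel, truncate_negative = FALSE)
  expect_equal(Kraw["A1", "A2"], 1)
  expect_equal(Kraw["A1", "A3"], -1)
  K <- loiselle_kinship(panel)
  expect_equal(K["A1", "A3"], 0)
  expect_equal(K["A3", "A4"], 1)
  expect_identical(unclass(K), t(unclass(K)))
})

test_that("kinship is invariant to duplicating every locus", {
  panel <- random_panel(n = 20, n_loci = 6, seed = 4)
  dup <- genotype_panel(
    cbind(panel$calls,
          `colnames<-`(panel$calls, paste0(colnames(panel$calls), "b"))),
    dplyr::bind_rows(panel$map,
                     dplyr::mutate(panel$map,
                                   marker_id = paste0(marker_id, "b"))))
  expect_equal(unclass(loiselle_kinship(dup)), unclass(loiselle_kinship(panel)))
})

test_that("a weakly related polymorphic panel has mostly near-zero kinship", {
  # low divergence, well-admixed lines, many alleles per locus: the kinship
  # distribution should concentrate below 0.05 as in typical germplasm panels
  fr <- vapply(1:3, function(s) {
    sim <- simulate_panel(sim_config(
      n_accessions = 150L, divergence_Fst = 0.05, admixture_alpha = 1,
      alleles_per_locus_range = c(4L, 9L), n_founder_haplotypes = 200L,
      n_ancestral_haplotypes = 40L, generations_of_mating = 30L, seed = s))
    K <- loiselle_kinship(sim$panel)
    mean(K[upper.tri(K)] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(fr >= 0.8))
})

test_that("structure marker thinning respects the minimum spacing", {
  sim <- simulate_panel(sim_config(n_accessions = 40L, n_loci = 40L,
                                   n_chromosomes = 4L, seed = 8))
  keep <- select_structure_markers(sim$panel, min_spacing_cM = 20)
  mp <- sim$panel$map[sim$panel$map$marker_id %in% keep, ]
  gaps <- mp |>
    dplyr::group_by(chromosome) |>
    dplyr::summarise(min_gap = min(diff(sort(position_cM)), Inf))
  expect_true(all(gaps$min_gap >= 20))
})
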