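mining_fixture <- function() {
  calls <- matrix(c(1L, 1L, 2L, 2L,
                    1L, 2L, 1L, 2L),
                  nrow = 4,
                  dimnames = list(paste0("A", 1:4), c("M1", "M2")))
  map <- tibble::tibble(marker_id = c("M1", "M2"), chromosome = c("C1", "C2"),
                        position_cM = c(0, 0))
  panel <- genotype_panel(calls, map)
  lm_across <- tibble::tibble(
    accession_id = paste0("A", 1:4),
    trait = "LY",
    value = c(10, 12, 8, 6)
  )
  list(panel = panel, lm = lm_across)
}

test_that("the allele effect is the carrier mean minus the panel mean", {
  fx <- mining_fixture()
  eff <- allele_effect(fx$lm, fx$panel, "M1", 1L, "LY")
  expect_equal(eff$a_i, mean(c(10, 12)) - mean(c(10, 12, 8, 6)))
  expect_equal(eff$a_i, 2)
  expect_equal(eff$n_carriers, 2L)
  # an allele carried by everyone has zero effect
  mono <- fx$panel
  mono$calls[, "M2"] <- 1L
  expect_equal(allele_effect(fx$lm, mono, "M2", 1L, "LY")$a_i, 0)
  # no phenotyped carrier: NA with a warning
  expect_warning(e3 <- allele_effect(fx$lm[1:2, ], fx$panel, "M1", 2L, "LY"),
                 "no phenotyped carrier")
  expect_true(is.na(e3$a_i))
})

test_that("carrier-weighted effects balance to zero on complete data", {
  fx <- mining_fixture()
  effs <- allele_effects(fx$lm, fx$panel,
                         tibble::tibble(marker_id = c("M1", "M2"),
                                        trait = "LY"))
  balance <- effs |>
    dplyr::group_by(marker_id) |>
    dplyr::summarise(s = sum(n_carriers * a_i))
  expect_equal(balance$s, c(0, 0), tolerance = 1e-12)
  # also on a random complete panel
  panel <- random_panel(n = 40, n_loci = 3, n_alleles = 4, seed = 5)
  lm_r <- tibble::tibble(accession_id = rownames(panel$calls), trait = "LY",
                         value = withr::with_seed(6, rnorm(40, 20, 5)))
  effs_r <- allele_effects(lm_r, panel,
                           tibble::tibble(marker_id = colnames(panel$calls),
                                          trait = "LY"))
  bal <- effs_r |>
    dplyr::group_by(marker_id) |>
    dplyr::summarise(s = sum(n_carriers * a_i))
  expect_equal(bal$s, rep(0, 3), tolerance = 1e-9)
})

test_that("favorable alleles follow the breeding-objective direction", {
  effects <- tibble::tibble(
    marker_id = "M", allele = 1:3,
    trait = c("LY", "SI", "LY"),
    a_i = c(2, -0.17, 0)
  )
  out <- favorable_alleles(effects)
  expect_equal(out$favorable, c(TRUE, TRUE, FALSE))
  expect_error(favorable_alleles(dplyr::mutate(effects, trait = "XX")),
               "no breeding objective")
})

test_that("representative accessions are ranked in the objective direction", {
  n <- 6
  calls <- matrix(1L, n, 1, dimnames = list(paste0("A", 1:n), "M1"))
  calls[5:6] <- 2L
  panel <- genotype_panel(calls, tibble::tibble(marker_id = "M1",
                                                chromosome = "C1",
                                                position_cM = 0))
  lm_ly <- tibble::tibble(accession_id = paste0("A", 1:n), trait = "LY",
                          value = c(30, 25, 28, 22, 40, 41))
  top <- representative_accessions(lm_ly, panel, "M1", 1L, "LY")
  expect_equal(top, c("A1", "A3", "A2"))
  # minimised trait: smallest first
  lm_si <- dplyr::mutate(lm_ly, trait = "SI")
  bottom <- representative_accessions(lm_si, panel, "M1", 1L, "SI")
  expect_equal(bottom, c("A4", "A2", "A3"))
  # only two carriers: a list of two
  expect_equal(representative_accessions(lm_ly, panel, "M1", 2L, "LY"),
               c("A6", "A5"))
  # ties break lexicographically
  lm_tie <- dplyr::mutate(lm_ly, value = c(30, 30, 30, 30, 1, 1))
  expect_equal(representative_accessions(lm_tie, panel, "M1", 1L, "LY"),
               c("A1", "A2", "A3"))
})

test_that("transmission classes reproduce the worked frequency rows", {
  tab <- example_frequency_table()
  groups <- c("I", "II", "III", "IV", "V", "VI")
  cls <- vapply(seq_len(nrow(tab)), function(i) {
    classify_transmission(tab$CK[i], unlist(tab[i, groups]))
  }, integer(1))
  # founder-fixed, underutilised and founder-absent exemplars
  expect_equal(cls[tab$marker_id == "JESPR135"], 1L)
  expect_equal(cls[tab$marker_id == "NAU3269"], 2L)
  expect_equal(cls[tab$marker_id == "NAU5166"], 3L)
  # class 3 exactly when absent from the founder group
  expect_equal(cls == 3L, tab$CK == 0)
  expect_error(classify_transmission(NA, c(0.5, 0.5)), "required")
  expect_error(classify_transmission(1.2, c(0.5, 0.5)), "0, 1")
})

test_that("transmission tables count typed lines per era group", {
  calls <- matrix(c(1L, 1L, 2L, 2L, 2L, NA),
                  nrow = 6, dimnames = list(paste0("A", 1:6), "M1"))
  panel <- genotype_panel(calls, tibble::tibble(marker_id = "M1",
                                                chromosome = "C1",
                                                position_cM = 0),
                          tiny_meta())
  tt <- transmission_table(panel, tibble::tibble(marker_id = "M1",
                                                 allele = 2L))
  expect_equal(tt$CK, 0)                       # A1 carries allele 1
  expect_equal(tt$I, 0.5)                      # A2 (1), A3 (2)
  expect_equal(tt$II, 1)                       # A4, A5 typed; A6 missing
  expect_equal(tt$Total, 3 / 5)
  expect_equal(tt$transmission_class, 3L)
  expect_error(
    transmission_table(panel, tibble::tibble(marker_id = "M1", allele = 9L)),
    "absent")
})

test_that("a simulated QTL shift is recovered as half its allele contrast", {
  withr::with_seed(71, {
    n <- 300
    x <- sample(1:2, n, replace = TRUE, prob = c(0.5, 0.5))
    delta <- 2
    y <- 20 + delta * (x == 2) + rnorm(n, 0, 1.5)
  })
  calls <- cbind(Mq = as.integer(x))
  rownames(calls) <- sprintf("A%03d", 1:n)
  panel <- genotype_panel(calls, tibble::tibble(marker_id = "Mq",
                                                chromosome = "C1",
                                                position_cM = 0))
  lm_across <- tibble::tibble(accession_id = rownames(calls), trait = "LY",
                              value = y)
  eff <- allele_effect(lm_across, panel, "Mq", 2L, "LY")
  p2 <- mean(x == 2)
  expect_lt(abs(eff$a_i - delta * (1 - p2)), 0.3)
  expect_gt(eff$a_i, 0)
})
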