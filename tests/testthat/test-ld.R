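two_locus_panel <- function(x, y) {
  calls <- cbind(Ma = x, Mb = y)
  rownames(calls) <- sprintf("A%02d", seq_along(x))
  genotype_panel(calls, tibble::tibble(marker_id = c("Ma", "Mb"),
                                       chromosome = "C1",
                                       position_cM = c(0, 5)))
}

test_that("r2 matches the haplotype closed forms", {
  # perfect coupling: AB, AB, ab, ab
  p <- two_locus_panel(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  expect_equal(pairwise_r2(p, "Ma", "Mb", rare_threshold = 0)$r2, 1)
  # independence: AB, Ab, aB, ab
  p0 <- two_locus_panel(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  expect_equal(pairwise_r2(p0, "Ma", "Mb", rare_threshold = 0)$r2, 0)
})

test_that("the weighted average collapses to plain r2 for biallelic pairs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- sample(1:2, 40, replace = TRUE)
      y <- sample(1:2, 40, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      plain <- cor(x == 1, y == 1)^2
      expect_equal(alleleminer:::weighted_r2(x, y), plain, tolerance = 1e-12)
    }
  })
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  withr::with_seed(12, {
    x <- sample(1:3, 60, replace = TRUE)
    y <- sample(1:4, 60, replace = TRUE)
    expect_equal(alleleminer:::weighted_r2(x, y),
                 alleleminer:::weighted_r2(y, x))
    relab <- c(3L, 1L, 2L)[x]  # permute labels at locus A
    expect_equal(alleleminer:::weighted_r2(relab, y),
                 alleleminer:::weighted_r2(x, y))
  })
})

test_that("biallelic p-values agree with exhaustive hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(ks, c1, n - c1, r1)
    p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(8:20, 1)
      x <- sample(1:2, n, replace = TRUE)
      y <- sample(1:2, n, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      p <- two_locus_panel(x, y)
      res <- pairwise_r2(p, "Ma", "Mb", rare_threshold = 0)
      expect_equal(res$p_value, enum_fisher(table(x, y)), tolerance = 1e-10)
    }
  })
})

test_that("rare alleles are masked before r2 and monomorphic pairs skipped", {
  x <- c(rep(1L, 30), 2L)          # allele 2 at freq 1/31 < 0.05
  y <- rep(c(1L, 2L), length.out = 31)
  p <- two_locus_panel(x, y)
  expect_warning(res <- pairwise_r2(p, "Ma", "Mb"), "monomorphic")
  expect_null(res)
  # with masking disabled the pair is computable
  expect_s3_class(pairwise_r2(p, "Ma", "Mb", rare_threshold = 0), "tbl_df")
})

test_that("permutation p-values are seeded and deterministic", {
  withr::with_seed(14, {
    x <- sample(1:3, 50, replace = TRUE)
    y <- sample(1:3, 50, replace = TRUE)
  })
  p <- two_locus_panel(x, y)
  a <- ld_pairs(p, n_perm = 100, seed = 99, rare_threshold = 0)
  b <- ld_pairs(p, n_perm = 100, seed = 99, rare_threshold = 0)
  expect_identical(a, b)
  expect_true(a$p_value > 0 && a$p_value <= 1)
})

test_that("ld_summary stratifies and counts significance correctly", {
  pairs <- tibble::tibble(
    marker_a = c("a", "a", "b"), marker_b = c("b", "c", "c"),
    n = 30, r2 = c(0.2, 0.2, 0.2), p_value = c(0.005, 0.5, 0.02),
    linked = c(TRUE, FALSE, FALSE),
    distance_cM = c(3, NA, NA)
  )
  s <- ld_summary(pairs, alpha = 0.01)
  expect_equal(s$mean_r2, rep(0.2, 3))
  expect_equal(s$pct_significant[s$stratum == "unlinked"], 0)
  expect_equal(s$pct_significant[s$stratum == "total"], 100 / 3)
  two <- pairs[1:2, ]
  expect_equal(ld_summary(two)$pct_significant[1], 50)
  expect_warning(ld_summary(pairs[pairs$linked, ]), "empty LD stratum")
})

test_that("the background percentile uses the nearest rank", {
  pairs <- tibble::tibble(r2 = seq(0.001, 0.1, by = 0.001),
                          linked = FALSE)
  expect_equal(background_ld(pairs), 0.099)
  const <- tibble::tibble(r2 = rep(0.04, 200), linked = FALSE)
  expect_equal(suppressWarnings(background_ld(const)), 0.04)
  # brute-force sort oracle, including an extreme outlier
  withr::with_seed(15, {
    for (n in c(100, 999, 5000)) {
      x <- runif(n)
      x[1] <- 50
      tbl <- tibble::tibble(r2 = x, linked = FALSE)
      expect_equal(background_ld(tbl), sort(x)[ceiling(0.99 * n)])
    }
  })
  expect_error(background_ld(tibble::tibble(r2 = 0.1, linked = TRUE)),
               "no unlinked")
  expect_warning(background_ld(tibble::tibble(r2 = rep(0.1, 10),
                                              linked = FALSE)),
                 "fewer than 100")
})

test_that("the decay fit recovers exact logarithmic data and its crossings", {
  d <- exp(seq(log(0.5), log(40), length.out = 30))
  pairs <- tibble::tibble(
    marker_a = "x", marker_b = "y", n = 100,
    r2 = 0.5 - 0.1 * log(d), p_value = 0.001,
    linked = TRUE, distance_cM = d
  )
  fit <- fit_decay(pairs, thresholds = c(bg = 0.2, low = 0.05))
  expect_equal(fit$a, 0.5, tolerance = 1e-10)
  expect_equal(fit$b, -0.1, tolerance = 1e-10)
  expect_equal(fit$crossings$distance_cM[1], exp(3), tolerance = 1e-8)
  expect_true(all(fit$crossings$reached))
  # threshold above the intercept crosses below d = 1: outside range
  fit2 <- fit_decay(dplyr::mutate(pairs, distance_cM = distance_cM + 1),
                    thresholds = c(high = 0.9))
  expect_false(fit2$crossings$reached)
  # a positive slope cannot reach any threshold
  up <- dplyr::mutate(pairs, r2 = 0.1 + 0.05 * log(d))
  expect_warning(fit3 <- fit_decay(up, thresholds = c(t = 0.2)),
                 "slope >= 0")
  expect_false(any(fit3$crossings$reached))
  # degenerate distances are refused
  same_d <- dplyr::mutate(pairs, distance_cM = 2)
  expect_error(fit_decay(same_d), "distinct distances")
})

test_that("decay fitting uses only significant linked pairs", {
  d <- exp(seq(log(1), log(30), length.out = 20))
  good <- tibble::tibble(marker_a = "x", marker_b = "y", n = 50,
                         r2 = 0.4 - 0.08 * log(d), p_value = 0.001,
                         linked = TRUE, distance_cM = d)
  noise <- tibble::tibble(marker_a = "p", marker_b = "q", n = 50,
                          r2 = 0.9, p_value = 0.5,
                          linked = TRUE, distance_cM = 3)
  fit <- fit_decay(dplyr::bind_rows(good, noise), thresholds = c(t = 0.1))
  expect_equal(fit$b, -0.08, tolerance = 1e-10)
  expect_equal(nrow(fit$data), 20)
})
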