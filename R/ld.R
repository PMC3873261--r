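# ---- multi-allelic r-squared -------------------------------------------------

# weighted multi-allelic r^2 from two aligned, non-missing call vectors.
# For each allele pair (i at A, j at B) the table is collapsed to 2x2 and
# r2_ij = (p_ij - p_i q_j)^2 / (p_i(1-p_i) q_j(1-q_j)); the reported value is
# the product-of-marginals weighted average sum_ij p_i q_j r2_ij.
weighted_r2 <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  p <- rowSums(pj)
  q <- colSums(pj)
  D <- pj - outer(p, q)
  denom <- outer(p * (1 - p), q * (1 - q))
  r2 <- D^2 / denom
  sum(outer(p, q) * r2)
}

#' Pairwise linkage disequilibrium between two multi-allelic markers
#'
#' Computes the weighted average of squared allelic correlations between two
#' loci on homozygous lines (calls treated as haplotypes). Rare alleles
#' (frequency below `rare_threshold` among that locus's typed lines) are
#' first masked to missing; pairwise-complete lines are then used and
#' frequencies recomputed. The p-value is a two-sided Fisher's exact test for
#' a biallelic-by-biallelic pair, otherwise a Monte-Carlo permutation test of
#' one locus (seeded by the session RNG; set a seed for reproducibility).
#'
#' @param panel A [genotype_panel()].
#' @param marker_a,marker_b Marker ids.
#' @param rare_threshold Allele frequency below which calls are masked.
#' @param n_perm Number of permutations for multi-allelic p-values.
#' @return A one-row tibble `(marker_a, marker_b, n, r2, p_value)`, or `NULL`
#'   (with a warning) when a locus is monomorphic after masking.
#' @export
pairwise_r2 <- function(panel, marker_a, marker_b, rare_threshold = 0.05,
                        n_perm = 200L) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- mask_rare(panel$calls[, marker_a], rare_threshold)
  y <- mask_rare(panel$calls[, marker_b], rare_threshold)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warn(paste0("pair (", marker_a, ", ", marker_b,
                ") skipped: locus monomorphic after rare-allele masking"))
    return(NULL)
  }
  r2 <- weighted_r2(x, y)
  if (length(unique(x)) == 2L && length(unique(y)) == 2L) {
    p <- fisher.test(table(x, y))$p.value
  } else {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (weighted_r2(sample(x), y) >= r2 - 1e-12) exceed <- exceed + 1L
    }
    p <- (1L + exceed) / (n_perm + 1L)
  }
  tibble::tibble(marker_a = marker_a, marker_b = marker_b,
                 n = length(x), r2 = r2, p_value = p)
}

mask_rare <- function(calls, rare_threshold) {
  typed <- !is.na(calls)
  if (!any(typed)) return(calls)
  tab <- table(calls[typed])
  rare <- as.integer(names(tab)[as.numeric(tab) / sum(typed) < rare_threshold])
  calls[calls %in% rare] <- NA_integer_
  calls
}

#' All pairwise LD values in a panel
#'
#' Evaluates [pairwise_r2()] for every marker pair and annotates linkage
#' (same chromosome) and map distance (linked pairs only).
#'
#' @inheritParams pairwise_r2
#' @param subset Optional accession subset (e.g. one subpopulation).
#' @param seed Optional seed for the permutation p-values.
#' @return A tibble of LD pairs: `marker_a`, `marker_b`, `n`, `r2`,
#'   `p_value`, `linked`, `distance_cM` (`NA` for unlinked pairs).
#' @export
ld_pairs <- function(panel, subset = NULL, rare_threshold = 0.05,
                     n_perm = 200L, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(subset)) panel <- subset_panel(panel, accessions = subset)
  mk <- colnames(panel$calls)
  chrom <- setNames(panel$map$chromosome, panel$map$marker_id)
  pos <- setNames(panel$map$position_cM, panel$map$marker_id)
  pairs <- with_seed(seed, {
    res <- vector("list", length(mk) * (length(mk) - 1L) / 2L)
    idx <- 0L
    for (i in seq_len(length(mk) - 1L)) {
      for (j in seq.int(i + 1L, length(mk))) {
        idx <- idx + 1L
        res[[idx]] <- suppressWarnings(
          pairwise_r2(panel, mk[i], mk[j], rare_threshold, n_perm))
      }
    }
    dplyr::bind_rows(res[!vapply(res, is.null, logical(1))])
  })
  if (nrow(pairs) == 0L) return(pairs)
  pairs |>
    dplyr::mutate(
      linked = chrom[.data$marker_a] == chrom[.data$marker_b],
      distance_cM = ifelse(.data$linked,
                           abs(pos[.data$marker_a] - pos[.data$marker_b]),
                           NA_real_)
    )
}

#' Stratified LD summary
#'
#' Mean r-squared and percentage of significant pairs for the total, linked
#' and unlinked strata (the standard panel-level LD table).
#'
#' @param pairs Output of [ld_pairs()].
#' @param alpha Significance level for an LD pair (default 0.01).
#' @return A tibble `(stratum, n_pairs, mean_r2, pct_significant)`.
#' @export
ld_summary <- function(pairs, alpha = 0.01) {
  strata <- list(total = rep(TRUE, nrow(pairs)),
                 linked = pairs$linked,
                 unlinked = !pairs$linked)
  purrr::imap_dfr(strata, function(sel, name) {
    sub <- pairs[sel, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warn(paste0("empty LD stratum '", name, "'"))
      return(tibble::tibble(stratum = name, n_pairs = 0L, mean_r2 = NA_real_,
                            pct_significant = NA_real_))
    }
    tibble::tibble(stratum = name, n_pairs = nrow(sub),
                   mean_r2 = mean(sub$r2),
                   pct_significant = 100 * mean(sub$p_value <= alpha))
  })
}

#' Background LD level
#'
#' Nearest-rank 99th percentile of r-squared among unlinked marker pairs,
#' the conventional threshold separating linkage-driven LD from background
#' association.
#'
#' @param pairs Output of [ld_pairs()] (or any tibble with `r2` and,
#'   optionally, `linked`).
#' @param probs Percentile (default 0.99).
#' @return The background r-squared value.
#' @export
background_ld <- function(pairs, probs = 0.99) {
  r2 <- if ("linked" %in% names(pairs)) pairs$r2[!pairs$linked] else pairs$r2
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0L) abort("no unlinked pairs for background LD")
  if (length(r2) < 100L) {
    warn("fewer than 100 unlinked pairs; background LD percentile is noisy")
  }
  nearest_rank_percentile(r2, probs)
}

#' Fit the logarithmic LD decay curve
#'
#' Least-squares fit of \eqn{r^2 = a + b \ln(d)} on linked pairs significant
#' at `sig_alpha`, with threshold-crossing distances \eqn{d^* =
#' \exp((t-a)/b)} for each requested r-squared threshold. A crossing is
#' reported only when the slope is negative and the crossing lies within
#' `[min(d), 10 max(d)]`; otherwise it is flagged not reached.
#'
#' @param pairs Output of [ld_pairs()].
#' @param thresholds Named or unnamed numeric vector of r-squared thresholds
#'   (e.g. the background level, 0.1, 0.2).
#' @param sig_alpha Significance filter applied before fitting.
#' @return A `ld_decay_fit` object: list with `a`, `b`, `model` (the `lm`),
#'   `crossings` tibble `(threshold, distance_cM, reached)`, `data`.
#' @export
fit_decay <- function(pairs, thresholds = c(0.1, 0.2), sig_alpha = 0.01) {
  dat <- dplyr::filter(pairs, .data$linked, .data$p_value <= sig_alpha,
                       .data$distance_cM > 0)
  if (nrow(dat) < 3L || length(unique(dat$distance_cM)) < 2L) {
    abort("decay fit needs >= 3 significant linked pairs at >= 2 distinct distances")
  }
  fit <- lm(r2 ~ log(distance_cM), data = dat)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  d_range <- range(dat$distance_cM)
  if (b >= 0) {
    warn("LD does not decay with distance (slope >= 0); no crossing reached")
  }
  cross <- purrr::imap_dfr(as.list(thresholds), function(t, nm) {
    d_star <- if (b < 0) exp((t - a) / b) else NA_real_
    reached <- is.finite(d_star) && d_star >= d_range[1] &&
      d_star <= 10 * d_range[2]
    tibble::tibble(
      threshold_label = if (is.character(nm) && nzchar(nm)) nm
                        else paste0("r2=", format(t)),
      threshold = t,
      distance_cM = if (reached) d_star else NA_real_,
      reached = reached
    )
  })
  structure(list(a = a, b = b, model = fit, crossings = cross, data = dat),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat("<ld_decay_fit> r2 =", format(x$a, digits = 4), "+",
      format(x$b, digits = 4), "* ln(d) on", nrow(x$data), "pairs\n")
  print(x$crossings)
  invisible(x)
}

#' @rdname fit_decay
#' @param x,object A `ld_decay_fit`.
#' @param ... Unused.
#' @export
tidy.ld_decay_fit <- function(x, ...) x$crossings

#' @rdname fit_decay
#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b,
                 r_squared = summary(x$model)$r.squared,
                 n_pairs = nrow(x$data))
}

#' @rdname fit_decay
#' @export
autoplot.ld_decay_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    distance_cM = exp(seq(log(min(dat$distance_cM)),
                          log(max(dat$distance_cM)), length.out = 200)))
  grid$r2 <- object$a + object$b * log(grid$distance_cM)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance_cM, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "genetic distance (cM)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
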