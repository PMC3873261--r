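#' Descriptive statistics for one trait
#'
#' Mean, sample SD, range and coefficient of variation over line means,
#' either within one environment or across environments (the usual
#' descriptive-table rows of a multi-environment trial).
#'
#' @param pheno Long-format phenotype tibble.
#' @param trait Trait name.
#' @param environment Environment id, or `NULL` for across-environment line
#'   means.
#' @return A one-row tibble `(trait, environment, n, mean, sd, min, max,
#'   cv_pct)`; `cv_pct` is `100 * sd / mean` (`NA` when the mean is 0).
#' @export
trait_summary <- function(pheno, trait, environment = NULL) {
  lm_tbl <- if (is.null(environment)) {
    suppressWarnings(line_means(pheno, "across_environments", traits = trait))
  } else {
    dplyr::filter(line_means(pheno, "per_environment", traits = trait),
                  .data$environment_id == environment)
  }
  vals <- lm_tbl$value[!is.na(lm_tbl$value)]
  if (length(vals) < 2L) abort("trait_summary needs >= 2 observations")
  m <- mean(vals); s <- sd(vals)
  tibble::tibble(
    trait = trait,
    environment = environment %||% "across",
    n = length(vals),
    mean = m, sd = s, min = min(vals), max = max(vals),
    cv_pct = if (m == 0) NA_real_ else 100 * s / m
  )
}

#' Two-factor ANOVA with variance components
#'
#' Replicated multi-environment ANOVA for one trait: genotype (G),
#' environment (E), replicate-within-environment (block), and G-by-E, with
#' variance components by equating observed and expected mean squares on
#' balanced (or near-balanced) data:
#' \deqn{\sigma^2_e = MS_{err};\quad \sigma^2_{GE} = (MS_{GE} - MS_{err})/r;}
#' \deqn{\sigma^2_G = (MS_G - MS_{GE})/(er);\quad
#'       \sigma^2_{block} = (MS_{R(E)} - MS_{err})/g;}
#' \deqn{\sigma^2_E = (MS_E - MS_{GE} - MS_{R(E)} + MS_{err})/(gr).}
#' Negative moment estimates are truncated to zero and flagged. G is tested
#' against G-by-E; G-by-E against the residual.
#'
#' @param pheno Long-format phenotype tibble.
#' @param trait Trait name.
#' @return A `variance_components` object: tibble of ANOVA lines (term, df,
#'   sum_sq, mean_sq, statistic, p_value) with attributes `components`
#'   (named vector), `truncated` (names of truncated components), `n_env`,
#'   `n_rep`, `n_geno`.
#' @export
anova_components <- function(pheno, trait) {
  ph <- dplyr::filter(validate_phenotypes(pheno), .data$trait == !!trait,
                      !is.na(.data$value))
  if (nrow(ph) == 0L) abort(paste0("no observations for trait '", trait, "'"))
  g <- length(unique(ph$accession_id))
  e <- length(unique(ph$environment_id))
  r <- length(unique(ph$replicate_id))
  if (e < 2L) {
    abort("single environment: G-by-E variance is inestimable")
  }
  counts <- table(ph$accession_id, ph$environment_id, ph$replicate_id)
  if (!all(counts == 1L)) {
    warn("unbalanced data: expected-mean-squares equations assume balance")
  }

  y <- ph$value
  grand <- mean(y)
  n <- length(y)
  mg <- tapply(y, ph$accession_id, mean)
  me <- tapply(y, ph$environment_id, mean)
  mge <- tapply(y, list(ph$accession_id, ph$environment_id), mean)
  mer <- tapply(y, list(ph$environment_id, ph$replicate_id), mean)

  ss_g <- e * r * sum((mg - grand)^2)
  ss_e <- g * r * sum((me - grand)^2)
  ss_ge <- r * sum((sweep(sweep(mge, 1, mg), 2, me) + grand)^2, na.rm = TRUE)
  ss_block <- g * sum(sweep(mer, 1, me)^2, na.rm = TRUE)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_g - ss_e - ss_ge - ss_block

  df_g <- g - 1L
  df_e <- e - 1L
  df_ge <- (g - 1L) * (e - 1L)
  df_block <- e * (r - 1L)
  df_err <- n - 1L - df_g - df_e - df_ge - df_block
  if (df_err <= 0L) abort("no residual degrees of freedom")

  ms <- c(G = ss_g / df_g, E = ss_e / df_e, GE = ss_ge / df_ge,
          block = ss_block / df_block, err = ss_err / df_err)

  f_g <- ms[["G"]] / ms[["GE"]]
  p_g <- pf(f_g, df_g, df_ge, lower.tail = FALSE)
  f_ge <- ms[["GE"]] / ms[["err"]]
  p_ge <- pf(f_ge, df_ge, df_err, lower.tail = FALSE)

  raw <- c(
    sigma2_G = (ms[["G"]] - ms[["GE"]]) / (e * r),
    sigma2_GE = (ms[["GE"]] - ms[["err"]]) / r,
    sigma2_E = (ms[["E"]] - ms[["GE"]] - ms[["block"]] + ms[["err"]]) / (g * r),
    sigma2_block = (ms[["block"]] - ms[["err"]]) / g,
    sigma2_e = ms[["err"]]
  )
  truncated <- names(raw)[raw < 0]
  comp <- pmax(raw, 0)

  tbl <- tibble::tibble(
    term = c("genotype", "environment", "genotype:environment",
             "replicate_in_environment", "residual"),
    df = c(df_g, df_e, df_ge, df_block, df_err),
    sum_sq = c(ss_g, ss_e, ss_ge, ss_block, ss_err),
    mean_sq = unname(ms),
    statistic = c(f_g, NA, f_ge, NA, NA),
    p_value = c(p_g, NA, p_ge, NA, NA)
  )
  structure(tbl, class = c("variance_components", class(tbl)),
            components = comp, truncated = truncated,
            n_env = e, n_rep = r, n_geno = g, trait = trait)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> trait:", attr(x, "trait"), "\n")
  NextMethod()
  comp <- attr(x, "components")
  cat("components:",
      paste(names(comp), format(comp, digits = 4), sep = "=", collapse = "  "),
      "\n")
  if (length(attr(x, "truncated"))) {
    cat("truncated to 0:", paste(attr(x, "truncated"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname anova_components
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @export
tidy.variance_components <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname anova_components
#' @export
glance.variance_components <- function(x, ...) {
  comp <- attr(x, "components")
  tibble::tibble(
    trait = attr(x, "trait"),
    sigma2_G = comp[["sigma2_G"]], sigma2_GE = comp[["sigma2_GE"]],
    sigma2_E = comp[["sigma2_E"]], sigma2_block = comp[["sigma2_block"]],
    sigma2_e = comp[["sigma2_e"]],
    h_B2 = heritability(x),
    n_env = attr(x, "n_env"), n_rep = attr(x, "n_rep"),
    n_geno = attr(x, "n_geno")
  )
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{h_B^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E +
#'       \sigma^2_e/(E r))}
#' with E environments and r replicates; clipped to `[0, 1]`.
#'
#' @param vc A `variance_components` object from [anova_components()], or a
#'   named vector with `sigma2_G`, `sigma2_GE`, `sigma2_e`.
#' @param n_env,n_rep Environment/replicate counts (taken from `vc` when it
#'   is a `variance_components` object).
#' @return Heritability in `[0, 1]` (`NA` when all components are zero).
#' @export
heritability <- function(vc, n_env = NULL, n_rep = NULL) {
  if (inherits(vc, "variance_components")) {
    n_env <- n_env %||% attr(vc, "n_env")
    n_rep <- n_rep %||% attr(vc, "n_rep")
    vc <- attr(vc, "components")
  }
  if (is.null(n_env) || is.null(n_rep)) abort("n_env and n_rep are required")
  sg <- vc[["sigma2_G"]]; sge <- vc[["sigma2_GE"]]; se <- vc[["sigma2_e"]]
  denom <- sg + sge / n_env + se / (n_env * n_rep)
  if (denom == 0) return(NA_real_)
  min(1, max(0, sg / denom))
}

#' Pairwise trait correlations on line means
#'
#' Pairwise-complete Pearson correlations between across-environment line
#' means, with t-test p-values and conventional significance stars
#' (`*` 0.05, `**` 0.01, `***` 0.001).
#'
#' @param lm_across Across-environment line means from [line_means()], or a
#'   raw phenotype table (detected by a `replicate_id` column and averaged
#'   first).
#' @return A tibble `(trait_a, trait_b, n, r, p_value, stars)` over
#'   unordered trait pairs; zero-variance traits give `NA` with a warning.
#' @export
trait_correlations <- function(lm_across) {
  if ("replicate_id" %in% names(lm_across)) {
    lm_across <- suppressWarnings(line_means(lm_across, "across_environments"))
  }
  wide <- lm_across |>
    dplyr::select("accession_id", "trait", "value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  traits <- setdiff(names(wide), "accession_id")
  combos <- utils::combn(traits, 2L, simplify = FALSE)
  purrr::map_dfr(combos, function(tt) {
    x <- wide[[tt[1]]]; y <- wide[[tt[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) abort("trait correlations need >= 3 complete lines per pair")
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(paste0("zero-variance trait in pair ", tt[1], "-", tt[2]))
      return(tibble::tibble(trait_a = tt[1], trait_b = tt[2], n = sum(ok),
                            r = NA_real_, p_value = NA_real_, stars = ""))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(
      trait_a = tt[1], trait_b = tt[2], n = sum(ok),
      r = unname(ct$estimate), p_value = ct$p.value,
      stars = dplyr::case_when(ct$p.value <= 0.001 ~ "***",
                               ct$p.value <= 0.01 ~ "**",
                               ct$p.value <= 0.05 ~ "*",
                               TRUE ~ "")
    )
  })
}
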