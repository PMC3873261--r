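# ---- Q+K mixed linear model marker scan -------------------------------------

#' Fit the null Q+K mixed model by REML
#'
#' Fits \eqn{y = \mu + Qv + u + e} with \eqn{Var(u) = \sigma^2_g K} and
#' \eqn{Var(e) = \sigma^2_e I} by restricted maximum likelihood, profiling a
#' single variance ratio \eqn{\lambda = \sigma^2_g/\sigma^2_e} over the
#' eigendecomposition of K (EMMA-style). The fit is deterministic given its
#' inputs. When the likelihood is flat in \eqn{\lambda} (e.g. `K = I`, where
#' only the total variance is identified), the \eqn{\sigma^2_g = 0} boundary
#' is chosen by convention; generalized least squares is unaffected.
#'
#' @param y Named numeric vector of line means (names = accession ids), or a
#'   tibble `(accession_id, value)`.
#' @param Q Optional matrix/data frame of structure covariates (accession
#'   rows). To avoid collinearity with the intercept, supply k-1 of the k
#'   admixture columns — [structure_covariates()] does this.
#' @param K Kinship matrix covering the accessions of `y`; must be positive
#'   semidefinite up to estimation noise. Sample kinship estimators with
#'   pairwise-complete loci and negative-value truncation are not exactly
#'   PSD, so eigenvalues down to `-psd_tol * max(eig)` are bent (clamped) to
#'   zero; anything more negative is a genuinely indefinite matrix and is
#'   rejected.
#' @param psd_tol Relative tolerance for bending negative eigenvalues
#'   (default 0.25; sample kinship from a hundred-odd loci routinely carries
#'   negative eigenvalues around a tenth of the leading one).
#' @param lambda_grid Log10 search grid bounds for the variance ratio.
#' @return An `mlm_fit` object: list with `sigma2_g`, `sigma2_e`, `lambda`,
#'   `loglik` (restricted), `beta` (fixed effects), `accession_ids`, `X`
#'   (null fixed-effect design), `V` (phenotypic covariance at the REML
#'   estimates), plus the eigendecomposition cache.
#' @export
fit_null_mlm <- function(y, Q = NULL, K, psd_tol = 0.25,
                         lambda_grid = c(-6, 6)) {
  if (is.data.frame(y)) y <- setNames(y$value, y$accession_id)
  if (is.null(names(y))) abort("`y` must carry accession ids as names")
  ids <- names(y)[!is.na(y)]
  y <- y[ids]
  K <- as.matrix(unclass(K))
  if (!all(ids %in% rownames(K))) abort("K does not cover all phenotyped accessions")
  K <- K[ids, ids]
  X <- cbind(`(Intercept)` = rep(1, length(ids)))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)
    if (!all(ids %in% rownames(Qm))) abort("Q does not cover all phenotyped accessions")
    Qm <- Qm[ids, , drop = FALSE]
    keep <- apply(Qm, 2, function(col) sd(col) > 1e-10)
    X <- cbind(X, Qm[, keep, drop = FALSE])
  }
  n <- length(y); q <- ncol(X)
  if (n < q + 2L) abort("too few accessions for the fixed-effect design")

  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -psd_tol * max(abs(eig$values), 1)) {
    abort("K is not positive semidefinite")
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  # reconstruct K from the bent spectrum so V = s2g*K + s2e*I stays PSD
  K <- U %*% (d * t(U))
  dimnames(K) <- list(ids, ids)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    beta <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - q)
    -0.5 * ((n - q) * (log(2 * pi * s2) + 1) + sum(log(lam * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus -
              determinant(crossprod(X), logarithm = TRUE)$modulus)
  }

  grid <- seq(lambda_grid[1] * log(10), lambda_grid[2] * log(10),
              length.out = 41L)
  vals <- vapply(grid, reml_ll, numeric(1))
  # flat profile (ratio unidentifiable): take the sigma2_g = 0 boundary
  if (diff(range(vals)) < 1e-8) {
    best_log_lambda <- -Inf
  } else {
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    best_log_lambda <- opt$maximum
    # boundary candidate must not beat the interior optimum
    if (reml_ll(grid[1]) > opt$objective) best_log_lambda <- -Inf
  }
  lam <- if (is.finite(best_log_lambda)) exp(best_log_lambda) else 0
  w <- 1 / (lam * d + 1)
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  s2e <- sum(w * r^2) / (n - q)
  s2g <- lam * s2e
  V <- s2g * K + diag(s2e, n)
  dimnames(V) <- list(ids, ids)
  ll <- if (is.finite(best_log_lambda)) reml_ll(best_log_lambda) else reml_ll(-50)

  structure(list(sigma2_g = s2g, sigma2_e = s2e, lambda = lam,
                 loglik = ll, beta = drop(beta), accession_ids = ids,
                 y = y, X = X, K = K, V = V,
                 eigen = list(values = d, vectors = U)),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("<mlm_fit> n =", length(x$y),
      " sigma2_g =", format(x$sigma2_g, digits = 4),
      " sigma2_e =", format(x$sigma2_e, digits = 4),
      " h2 =", format(x$sigma2_g / (x$sigma2_g + x$sigma2_e), digits = 3),
      "\n")
  invisible(x)
}

#' @rdname fit_null_mlm
#' @param x,object An `mlm_fit`.
#' @param ... Unused.
#' @export
tidy.mlm_fit <- function(x, ...) {
  tibble::tibble(term = colnames(x$X), estimate = unname(x$beta))
}

#' @rdname fit_null_mlm
#' @export
glance.mlm_fit <- function(x, ...) {
  tibble::tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                 lambda = x$lambda,
                 h2 = x$sigma2_g / (x$sigma2_g + x$sigma2_e),
                 loglik = x$loglik, n = length(x$y))
}

#' Structure covariates for the mixed model
#'
#' Drops the last admixture column of a Q matrix (rows sum to 1, so one
#' column is redundant with the intercept).
#'
#' @param Q Admixture proportion matrix.
#' @return Matrix with k-1 columns.
#' @export
structure_covariates <- function(Q) {
  Q <- as.matrix(Q)
  if (ncol(Q) < 2L) return(Q[, 0, drop = FALSE])
  Q[, -ncol(Q), drop = FALSE]
}

#' Scan markers against a fitted null mixed model
#'
#' P3D-style generalized least squares: the null variance components are
#' reused for every marker. Each marker enters as a categorical fixed effect
#' (one class per retained allele; lines are homozygous). Alleles below
#' `min_allele_freq` among the marker's complete cases are pooled into an
#' "other" class (`rare_policy = "pool"`), dropped (`"drop"`), or kept
#' (`"none"`). Lines missing the marker call are dropped for that marker
#' only, with the covariance restricted accordingly. The F statistic
#' compares the marker model with the null on the whitened (decorrelated)
#' scale; `marker_r2` is `(RSS_null - RSS_marker)/TSS` on that scale, with
#' TSS the whitened residual sum of squares about the whitened intercept.
#'
#' @param fit An [fit_null_mlm()] result.
#' @param panel A [genotype_panel()].
#' @param markers Marker ids to test (default: all in the panel).
#' @param rare_policy `"pool"`, `"drop"` or `"none"`.
#' @param min_allele_freq Frequency threshold defining a rare allele class.
#' @return A tibble: `marker_id`, `n`, `df`, `f_statistic`, `p_value`,
#'   `neg_log10_p`, `marker_r2`. Markers monomorphic among complete cases
#'   are skipped with a message.
#' @export
marker_scan <- function(fit, panel, markers = NULL,
                        rare_policy = c("pool", "drop", "none"),
                        min_allele_freq = 0.05) {
  stopifnot(inherits(fit, "mlm_fit"), inherits(panel, "genotype_panel"))
  rare_policy <- match.arg(rare_policy)
  markers <- markers %||% colnames(panel$calls)
  ids <- fit$accession_ids
  calls_all <- panel$calls[ids, , drop = FALSE]
  # cache the whitening factor for markers with no missing calls
  Uc_full <- chol(fit$V)

  purrr::map_dfr(markers, function(m) {
    x <- calls_all[, m]
    keep <- !is.na(x)
    x <- encode_marker(x[keep], rare_policy, min_allele_freq)
    if (is.null(x)) {
      inform(paste0("marker_scan: skipping ", m,
                    " (monomorphic among complete cases)"))
      return(NULL)
    }
    keep_ids <- ids[keep][!is.na(x)]
    x <- x[!is.na(x)]
    yv <- fit$y[keep_ids]
    X0 <- fit$X[match(keep_ids, ids), , drop = FALSE]
    if (length(unique(x)) < 2L) {
      inform(paste0("marker_scan: skipping ", m,
                    " (monomorphic among complete cases)"))
      return(NULL)
    }
    Uc <- if (length(keep_ids) == length(ids)) Uc_full
          else chol(fit$V[keep_ids, keep_ids])
    yw <- backsolve(Uc, yv, transpose = TRUE)
    Xw0 <- backsolve(Uc, X0, transpose = TRUE)
    Mx <- stats::model.matrix(~ factor(x))[, -1, drop = FALSE]
    Xw1 <- cbind(Xw0, backsolve(Uc, Mx, transpose = TRUE))
    q0 <- qr(Xw0); q1 <- qr(Xw1)
    rss0 <- sum(qr.resid(q0, yw)^2)
    rss1 <- sum(qr.resid(q1, yw)^2)
    onew <- backsolve(Uc, rep(1, length(yv)), transpose = TRUE)
    tss <- sum(qr.resid(qr(cbind(onew)), yw)^2)
    df1 <- q1$rank - q0$rank
    df2 <- length(yv) - q1$rank
    if (df1 < 1L || df2 < 1L) return(NULL)
    fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(fstat, df1, df2, lower.tail = FALSE)
    tibble::tibble(marker_id = m, n = length(yv), df = df1,
                   f_statistic = fstat, p_value = p,
                   neg_log10_p = -log10(p),
                   marker_r2 = (rss0 - rss1) / tss)
  })
}

# recode a complete-case call vector according to the rare-allele policy;
# returns NULL if monomorphic, otherwise an integer/character vector with NAs
# where calls were dropped
encode_marker <- function(x, rare_policy, min_allele_freq) {
  tab <- table(x)
  if (length(tab) < 2L) return(NULL)
  freqs <- as.numeric(tab) / length(x)
  rare <- names(tab)[freqs < min_allele_freq]
  out <- as.character(x)
  if (length(rare) > 0 && rare_policy == "pool") {
    out[out %in% rare] <- "other"
  } else if (length(rare) > 0 && rare_policy == "drop") {
    out[out %in% rare] <- NA_character_
  }
  if (length(unique(out[!is.na(out)])) < 2L) return(NULL)
  out
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' \eqn{-\log_{10}(\alpha/m)} for m tests at family-wise level alpha; for
#' the conventional 145-marker scan at alpha = 0.05 this is 3.46 (2 dp).
#' The exact value is returned; rounding is left to table formatting.
#'
#' @param m Number of tests (markers), >= 1.
#' @param alpha Family-wise error rate in (0, 1).
#' @return The threshold on the -log10 p scale.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1L) abort("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  -log10(alpha / m)
}

#' Multi-environment association scan
#'
#' Runs the Q+K mixed-model scan for every trait and environment: per
#' trait-environment the null model is fitted once by REML
#' ([fit_null_mlm()]) and all markers are tested by generalized least
#' squares ([marker_scan()]). Bonferroni significance and multi-environment
#' stability flags are attached via [stability_filter()].
#'
#' @param panel A [genotype_panel()].
#' @param pheno Long-format phenotype tibble.
#' @param Q Structure covariate matrix (already reduced to k-1 columns, see
#'   [structure_covariates()]), or `NULL` for intercept-only.
#' @param K Kinship matrix.
#' @param traits,environments Subsets to scan (default: all present).
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param env_alpha Per-environment detection level used by the stability
#'   rule.
#' @param min_env Environments required for a stable association.
#' @param ... Passed to [marker_scan()] (`rare_policy`, `min_allele_freq`).
#' @return A tibble of per marker-trait-environment records with columns of
#'   [marker_scan()] plus `trait`, `environment`, `significant_bonferroni`,
#'   `n_env_detected`, `stable`.
#' @export
association_scan <- function(panel, pheno, Q = NULL, K, traits = NULL,
                             environments = NULL, alpha = 0.05,
                             env_alpha = 0.01, min_env = 2L, ...) {
  lm_env <- line_means(pheno, "per_environment")
  traits <- traits %||% unique(lm_env$trait)
  environments <- environments %||% unique(lm_env$environment_id)
  records <- purrr::map_dfr(traits, function(tr) {
    purrr::map_dfr(environments, function(env) {
      cell <- dplyr::filter(lm_env, .data$trait == tr,
                            .data$environment_id == env, !is.na(.data$value))
      if (nrow(cell) == 0L) return(NULL)
      fit <- fit_null_mlm(setNames(cell$value, cell$accession_id), Q, K)
      dplyr::mutate(marker_scan(fit, panel, ...),
                    trait = tr, environment = env, .before = 1)
    })
  })
  stability_filter(records, m = ncol(panel$calls), alpha = alpha,
                   env_alpha = env_alpha, min_env = min_env)
}

#' Bonferroni and multi-environment stability flags
#'
#' Takes per marker-trait-environment scan records and flags (i)
#' `significant_bonferroni`: p at or below `alpha/m` in that environment;
#' (ii) `n_env_detected`: environments where the marker-trait pair reaches
#' the per-environment detection level `env_alpha`; (iii) `stable`: the pair
#' passes Bonferroni in at least one environment and is detected in at least
#' `min_env` environments. The per-environment detection level is
#' deliberately laxer than the Bonferroni gate: a stable association is one
#' that clears the multiple-testing hurdle somewhere and reproduces at the
#' nominal scan level elsewhere.
#'
#' @param records Tibble with columns `marker_id`, `trait`, `environment`,
#'   and `neg_log10_p` (or `p_value`).
#' @param m Number of markers tested (Bonferroni denominator).
#' @param alpha Family-wise level (default 0.05).
#' @param env_alpha Per-environment detection level (default 0.01).
#' @param min_env Environments required for stability (default 2).
#' @return The records with flag columns added.
#' @export
stability_filter <- function(records, m, alpha = 0.05, env_alpha = 0.01,
                             min_env = 2L) {
  if (!"neg_log10_p" %in% names(records)) {
    records$neg_log10_p <- -log10(records$p_value)
  }
  thr_bonf <- bonferroni_threshold(m, alpha)
  thr_env <- -log10(env_alpha)
  records |>
    dplyr::mutate(
      significant_bonferroni = !is.na(.data$neg_log10_p) &
        .data$neg_log10_p >= thr_bonf,
      detected_env = !is.na(.data$neg_log10_p) & .data$neg_log10_p >= thr_env
    ) |>
    dplyr::group_by(.data$marker_id, .data$trait) |>
    dplyr::mutate(
      n_env_detected = sum(.data$detected_env),
      stable = any(.data$significant_bonferroni) &
        .data$n_env_detected >= min_env
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"detected_env")
}

#' Summarise an association scan at the marker-trait level
#'
#' Collapses per-environment records to one row per marker-trait pair that
#' passes Bonferroni in at least one environment (the association table of a
#' germplasm scan), with the stability flag and detection counts.
#'
#' @inheritParams stability_filter
#' @return A list with `associations` (tibble, one row per significant
#'   marker-trait pair: best environment, `n_env_detected`, `stable`) and
#'   `summary` (tibble: `n_associations`, `n_markers`, `n_stable`,
#'   `pct_stable`).
#' @export
association_summary <- function(records, m, alpha = 0.05, env_alpha = 0.01,
                                min_env = 2L) {
  flagged <- stability_filter(records, m, alpha, env_alpha, min_env)
  assoc <- flagged |>
    dplyr::filter(!is.na(.data$neg_log10_p)) |>
    dplyr::group_by(.data$marker_id, .data$trait) |>
    dplyr::summarise(
      any_bonferroni = any(.data$significant_bonferroni),
      best_env = .data$environment[which.max(.data$neg_log10_p)],
      max_neg_log10_p = max(.data$neg_log10_p),
      n_env_detected = .data$n_env_detected[1],
      stable = .data$stable[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$any_bonferroni) |>
    dplyr::select(-"any_bonferroni")
  list(
    associations = assoc,
    summary = tibble::tibble(
      n_associations = nrow(assoc),
      n_markers = length(unique(assoc$marker_id)),
      n_stable = sum(assoc$stable),
      pct_stable = if (nrow(assoc) == 0) NA_real_
                   else 100 * sum(assoc$stable) / nrow(assoc)
    )
  )
}
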