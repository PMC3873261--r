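#' Evanno delta-k model selection
#'
#' Given replicate log-probabilities of the data LnP(D) from a model-based
#' clustering run over a range of assumed subpopulation numbers k, computes
#' the Evanno second-difference statistic
#' \deqn{\Delta k = |\bar L(k+1) - 2\bar L(k) + \bar L(k-1)| / sd(L(k))}
#' for every interior k, and chooses the k that maximises it (ties broken
#' toward smaller k, with a warning). LnP(D) often increases monotonically in
#' k with no peak; the curvature statistic still localises the dominant level
#' of structure.
#'
#' @param lnp_runs A data frame with columns `k` (integer) and `lnpd`
#'   (replicate LnP(D) values), or a named list `k -> numeric vector`.
#' @return A `k_selection` object: tibble `(k, n_runs, mean_lnpd, sd_lnpd,
#'   delta_k)` with attribute `chosen_k`.
#' @export
delta_k <- function(lnp_runs) {
  if (is.list(lnp_runs) && !is.data.frame(lnp_runs)) {
    lnp_runs <- tibble::tibble(
      k = rep(as.integer(names(lnp_runs)), lengths(lnp_runs)),
      lnpd = unlist(lnp_runs, use.names = FALSE)
    )
  }
  lnp_runs <- tibble::as_tibble(lnp_runs)
  if (!all(c("k", "lnpd") %in% names(lnp_runs))) {
    abort("lnp_runs needs columns `k` and `lnpd`")
  }
  stats_tbl <- lnp_runs |>
    dplyr::group_by(k = as.integer(.data$k)) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_lnpd = mean(.data$lnpd),
                     sd_lnpd = sd(.data$lnpd), .groups = "drop") |>
    dplyr::arrange(.data$k)
  ks <- stats_tbl$k
  if (length(ks) < 3L || !all(diff(ks) == 1L)) {
    abort("delta-k needs >= 3 consecutive k values")
  }
  interior <- ks[-c(1L, length(ks))]
  dk <- rep(NA_real_, nrow(stats_tbl))
  for (i in seq_along(ks)) {
    if (!ks[i] %in% interior) next
    if (stats_tbl$n_runs[i] < 2L) {
      abort(paste0("k = ", ks[i], " needs >= 2 replicates for delta-k"))
    }
    if (!is.finite(stats_tbl$sd_lnpd[i]) || stats_tbl$sd_lnpd[i] == 0) {
      abort(paste0("sd of LnP(D) is zero at k = ", ks[i]))
    }
    dk[i] <- abs(stats_tbl$mean_lnpd[i + 1L] - 2 * stats_tbl$mean_lnpd[i] +
                   stats_tbl$mean_lnpd[i - 1L]) / stats_tbl$sd_lnpd[i]
  }
  stats_tbl$delta_k <- dk
  best <- max(dk, na.rm = TRUE)
  cand <- ks[!is.na(dk) & dk == best]
  if (length(cand) > 1L) {
    warn(paste0("delta-k tie at k = {", paste(cand, collapse = ", "),
                "}; choosing the smaller k"))
  }
  structure(stats_tbl, class = c("k_selection", class(stats_tbl)),
            chosen_k = min(cand))
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> chosen k =", attr(x, "chosen_k"), "\n")
  NextMethod()
}

#' @rdname delta_k
#' @param x A `k_selection` object.
#' @param ... Unused.
#' @export
tidy.k_selection <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname delta_k
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(chosen_k = attr(x, "chosen_k"),
                 max_delta_k = max(x$delta_k, na.rm = TRUE),
                 k_range = paste(range(x$k), collapse = "-"))
}

#' @rdname delta_k
#' @param object A `k_selection` object.
#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df[!is.na(df$delta_k), ],
                  ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"),
                        linetype = "dashed") +
    ggplot2::labs(x = "assumed number of subpopulations (k)",
                  y = expression(Delta * k)) +
    ggplot2::theme_minimal()
}

#' Assign accessions to subpopulations from a Q matrix
#'
#' An accession goes to the subpopulation whose membership coefficient
#' exceeds 0.5 (strict); otherwise it is flagged admixed.
#'
#' @param Q Numeric matrix (accessions x subpopulations), rows summing to 1
#'   within `1e-6`; rownames are accession ids.
#' @param threshold Membership needed for assignment (default 0.5, strict).
#' @return A tibble `(accession_id, subpop, max_q)`; `subpop` is `"ADMIXED"`
#'   when no coefficient exceeds the threshold.
#' @export
assign_subpopulations <- function(Q, threshold = 0.5) {
  Q <- as.matrix(Q)
  if (any(abs(rowSums(Q) - 1) > 1e-6)) {
    abort("Q rows must sum to 1 (tolerance 1e-6)")
  }
  ids <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  j <- max.col(Q, ties.method = "first")
  q <- Q[cbind(seq_len(nrow(Q)), j)]
  tibble::tibble(
    accession_id = ids,
    subpop = ifelse(q > threshold, paste0("P", j), "ADMIXED"),
    max_q = q
  )
}

#' Estimate admixture proportions by EM
#'
#' A lightweight maximum-likelihood admixture model for homozygous (haploid-
#' equivalent) calls: the log-likelihood \eqn{\sum_i \sum_l \log \sum_c
#' q_{ic} f_{cl}(a_{il})} is maximised by EM block updates on the accession
#' admixture proportions q and the per-cluster allele frequencies f. This is
#' a fast convenience surrogate for full Bayesian MCMC clustering; the
#' canonical path is importing an externally computed Q matrix
#' ([read_q_matrix()]).
#'
#' @param panel A [genotype_panel()] (or integer call matrix).
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed for the random restarts.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `max_iter` iterations.
#' @param n_init Number of random restarts; the best likelihood wins.
#' @param pseudocount Frequency floor guarding against zero likelihoods.
#' @return A `structure_em` object: list with `Q` (matrix, rows sum to 1),
#'   `freqs`, `loglik` (final), `trace` (per-iteration log-likelihoods of the
#'   winning restart), `k`.
#' @export
estimate_Q_em <- function(panel, k, seed = 1L, max_iter = 300L, tol = 1e-6,
                          n_init = 3L, pseudocount = 1e-6) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else panel
  n <- nrow(calls); L <- ncol(calls)
  if (n == 0L || L == 0L) abort("empty panel")
  if (k < 1L) abort("k must be >= 1")
  if (k > n) abort("k exceeds the number of accessions")
  A <- max(calls, na.rm = TRUE)
  obs <- !is.na(calls)
  # indicator matrices per allele code, used for the f updates
  ind <- lapply(seq_len(A), function(a) (!is.na(calls)) & calls == a)
  idx <- cbind(rep(seq_len(L), each = n), as.vector(calls)) # (locus, allele)

  run_once <- function() {
    Q <- rdirichlet(n, rep(1, k))
    f <- lapply(seq_len(k), function(c) {
      fm <- matrix(0, L, A)
      for (a in seq_len(A)) fm[, a] <- colSums(ind[[a]]) + runif(L, 0, 1)
      fm / rowSums(fm)
    })
    trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      # E step: per-component likelihood of each (accession, locus) cell
      M <- lapply(seq_len(k), function(c) {
        m <- matrix(f[[c]][idx], n, L)
        m[!obs] <- 1
        m * Q[, c]
      })
      D <- Reduce(`+`, M)
      ll <- sum(log(D[obs]))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll < ll_old - 1e-8) {
        abort("EM log-likelihood decreased; numerical failure")
      }
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
      # M step
      Rs <- lapply(M, function(m) {
        r <- m / D
        r[!obs] <- 0
        r
      })
      Q <- sapply(Rs, rowSums) / pmax(rowSums(obs), 1)
      Q <- matrix(Q, n, k)
      Q <- Q / rowSums(Q)
      for (c in seq_len(k)) {
        fm <- matrix(pseudocount, L, A)
        for (a in seq_len(A)) fm[, a] <- fm[, a] + colSums(Rs[[c]] * ind[[a]])
        f[[c]] <- fm / rowSums(fm)
      }
    }
    list(Q = Q, f = f, loglik = trace[length(trace)], trace = trace)
  }

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(max(1L, n_init))) {
      fit <- run_once()
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  rownames(best$Q) <- rownames(calls)
  colnames(best$Q) <- paste0("Q", seq_len(k))
  structure(list(Q = best$Q, freqs = best$f, loglik = best$loglik,
                 trace = best$trace, k = k),
            class = "structure_em")
}

#' @export
print.structure_em <- function(x, ...) {
  cat("<structure_em> k =", x$k, " log-likelihood =",
      format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
tidy.structure_em <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "accession_id") |>
    tidyr::pivot_longer(-"accession_id", names_to = "cluster",
                        values_to = "q")
}

#' @export
glance.structure_em <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, n_iter = length(x$trace))
}

#' Read a Q matrix or LnP(D) replicate table
#'
#' `read_q_matrix()` reads a delimited table whose first column is the
#' accession label and remaining k columns are admixture proportions.
#' `read_lnpd_table()` reads a two-column `(k, lnpd)` replicate table.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A matrix (Q) or tibble (LnP(D) replicates).
#' @export
read_q_matrix <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  Q <- as.matrix(df[, -1, drop = FALSE])
  rownames(Q) <- as.character(df[[1]])
  if (any(abs(rowSums(Q) - 1) > 1e-6)) {
    abort("Q rows must sum to 1 (tolerance 1e-6)")
  }
  Q
}

#' @rdname read_q_matrix
#' @export
read_lnpd_table <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, col_types = "id",
                          progress = FALSE, show_col_types = FALSE)
  names(df) <- c("k", "lnpd")
  df
}

#' Thin markers for structure analysis
#'
#' Picks a spatially thinned marker subset (default one marker per 20 cM per
#' chromosome) so that the clustering sees unlinked or weakly linked loci.
#'
#' @param panel A [genotype_panel()].
#' @param min_spacing_cM Minimum map distance between retained markers.
#' @return Character vector of retained marker ids.
#' @export
select_structure_markers <- function(panel, min_spacing_cM = 20) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel$map |>
    dplyr::arrange(.data$chromosome, .data$position_cM) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_map(function(df, key) {
      keep <- character(0)
      last <- -Inf
      for (i in seq_len(nrow(df))) {
        if (df$position_cM[i] - last >= min_spacing_cM) {
          keep <- c(keep, df$marker_id[i])
          last <- df$position_cM[i]
        }
      }
      keep
    }) |>
    unlist()
}
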