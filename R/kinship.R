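#' Loiselle pairwise kinship
#'
#' Multi-allelic kinship estimator of Loiselle et al. (1995) for homozygous
#' lines, the common choice for germplasm panels:
#' \deqn{F_{ij} = \frac{\sum_l \sum_a (x_{ila} - p_{la})(x_{jla} - p_{la})}
#'                     {\sum_l \sum_a p_{la}(1 - p_{la})}}
#' where \eqn{x_{ila}} is accession i's frequency of allele a at locus l (0 or
#' 1 for homozygotes) and \eqn{p_{la}} the panel frequency. Loci missing in
#' either member of a pair are dropped pairwise (numerator and denominator).
#' Negative estimates are truncated to zero, the standard practice when the
#' matrix feeds a mixed model. The small-sample correction term is omitted by
#' default; `bias_correction = TRUE` adds the Loiselle
#' \eqn{\sum_l \sum_a p_{la}(1-p_{la})/(n_l - 1)} numerator term.
#'
#' @param panel A [genotype_panel()] with >= 2 accessions and >= 1
#'   polymorphic locus.
#' @param truncate_negative Truncate negative kinship at zero (default TRUE).
#' @param bias_correction Add the small-sample correction (default FALSE).
#' @return A symmetric accession-by-accession matrix of class
#'   `kinship_matrix`. Pairs sharing no typed locus are `NA` (with a
#'   warning).
#' @export
loiselle_kinship <- function(panel, truncate_negative = TRUE,
                             bias_correction = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n <- nrow(calls)
  if (n < 2L) abort("kinship needs >= 2 accessions")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  any_poly <- FALSE
  for (l in seq_len(ncol(calls))) {
    x <- calls[, l]
    typed <- !is.na(x)
    nt <- sum(typed)
    if (nt < 2L) next
    tab <- table(x[typed])
    p <- as.numeric(tab) / nt
    if (length(p) < 2L) next
    any_poly <- TRUE
    alleles <- as.integer(names(tab))
    # centered indicator matrix: n x alleles, missing rows zeroed
    C <- matrix(0, n, length(alleles))
    for (a in seq_along(alleles)) {
      C[typed, a] <- (x[typed] == alleles[a]) - p[a]
    }
    w <- sum(p * (1 - p))
    corr <- if (bias_correction) w / (nt - 1) else 0
    contrib <- tcrossprod(C) + corr * tcrossprod(typed + 0)
    num <- num + contrib * tcrossprod(typed + 0)
    den <- den + w * tcrossprod(typed + 0)
  }
  if (!any_poly) abort("kinship needs >= 1 polymorphic locus")
  K <- num / den
  if (any(den == 0)) {
    warn("some accession pairs share no typed polymorphic locus; kinship NA")
    K[den == 0] <- NA_real_
  }
  if (truncate_negative) {
    off <- row(K) != col(K)
    K[off & !is.na(K) & K < 0] <- 0
  }
  dimnames(K) <- list(rownames(calls), rownames(calls))
  structure(K, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", nrow(x), " accessions; mean off-diagonal ",
      sprintf("%.4f", mean(x[row(x) != col(x)], na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Tidy a kinship matrix into pair records
#'
#' @param x A `kinship_matrix`.
#' @param ... Unused.
#' @return A tibble `(accession_a, accession_b, kinship)` over unordered
#'   pairs (a < b).
#' @export
tidy.kinship_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(accession_a = ids[idx[, 1]],
                 accession_b = ids[idx[, 2]],
                 kinship = x[idx])
}

#' Write/read a square matrix as TSV
#'
#' @param mat Matrix with dimnames (kinship or Q).
#' @param path File path.
#' @return The path (write) or matrix (read).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(as.matrix(unclass(mat)), rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
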