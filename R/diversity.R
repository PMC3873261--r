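#' Allele frequencies at one marker
#'
#' Frequencies are computed over typed (non-missing) calls only, optionally
#' within a subset of accessions, and sum to 1.
#'
#' @param panel A [genotype_panel()].
#' @param marker A marker id present in the panel.
#' @param subset Optional character vector of accession ids.
#' @return A named numeric vector, names = allele codes.
#' @export
allele_frequencies <- function(panel, marker, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!marker %in% colnames(panel$calls)) {
    abort(paste0("marker '", marker, "' not in panel"))
  }
  calls <- panel$calls[subset %||% rownames(panel$calls), marker]
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) abort("all calls missing for this marker/subset")
  tab <- table(calls)
  setNames(as.numeric(tab) / length(calls), names(tab))
}

#' Gene diversity (expected heterozygosity)
#'
#' \eqn{H_e = 1 - \sum_i p_i^2}, the probability that two alleles drawn at
#' random differ. The uncorrected form is used (no \eqn{n/(n-1)} small-sample
#' factor).
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return Gene diversity in `[0, 1 - 1/k]`.
#' @export
gene_diversity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Polymorphism information content
#'
#' Botstein's PIC: \eqn{1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}. Always
#' bounded above by gene diversity, and 0 for a monomorphic locus.
#'
#' @inheritParams gene_diversity
#' @return PIC value in `[0, 1]`.
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  p2 <- freqs^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) abort("empty frequency vector")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6) {
    abort("allele frequencies must be non-negative and sum to 1")
  }
  invisible(freqs)
}

#' Per-locus diversity statistics
#'
#' One row per marker: typed-line count, allele count, gene diversity, PIC,
#' and the rare (frequency < `rare_threshold`) and unique (carried by exactly
#' one accession) allele counts.
#'
#' @param panel A [genotype_panel()].
#' @param subset Optional accession subset.
#' @param rare_threshold Frequency below which an allele is "rare" (strict).
#' @return A tibble with one row per marker; `rare_alleles`/`unique_alleles`
#'   are list-columns of allele codes.
#' @export
locus_diversity <- function(panel, subset = NULL, rare_threshold = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  acc <- subset %||% rownames(panel$calls)
  purrr::map_dfr(colnames(panel$calls), function(m) {
    calls <- panel$calls[acc, m]
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L) {
      return(tibble::tibble(marker_id = m, n_typed = 0L, n_alleles = 0L,
                            gene_diversity = NA_real_, pic = NA_real_,
                            rare_alleles = list(integer()),
                            unique_alleles = list(integer())))
    }
    tab <- table(calls)
    p <- as.numeric(tab) / length(calls)
    codes <- as.integer(names(tab))
    tibble::tibble(
      marker_id = m,
      n_typed = length(calls),
      n_alleles = length(p),
      gene_diversity = gene_diversity(p),
      pic = pic(p),
      rare_alleles = list(codes[p < rare_threshold]),
      unique_alleles = list(codes[as.integer(tab) == 1L])
    )
  })
}

#' Diversity summarised by accession group
#'
#' Computes per-locus diversity within each era group (or any grouping column
#' of the metadata) plus group-level means: total alleles, mean alleles per
#' locus, mean gene diversity and mean PIC. The identity `total alleles =
#' mean alleles/locus * n_loci` holds by construction.
#'
#' @param panel A [genotype_panel()] with metadata attached (or `meta` given).
#' @param meta Optional metadata tibble overriding `panel$meta`.
#' @param group Metadata column to group by (default `era_group`).
#' @return A list with `per_locus` (tibble: group x marker stats) and
#'   `summary` (one row per group).
#' @export
diversity_by_group <- function(panel, meta = NULL, group = "era_group") {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- tibble::as_tibble(meta %||% panel$meta)
  if (is.null(meta) || nrow(meta) == 0L) abort("no accession metadata available")
  if (!group %in% names(meta)) abort(paste0("unknown grouping column '", group, "'"))
  groups <- meta[[group]]
  present <- unique(as.character(groups[!is.na(groups)]))
  per_locus <- purrr::map_dfr(present, function(g) {
    ids <- meta$accession_id[as.character(groups) == g & !is.na(groups)]
    if (length(ids) == 0L) abort(paste0("empty group '", g, "'"))
    dplyr::mutate(locus_diversity(panel, subset = ids), group = g,
                  .before = 1)
  })
  summary <- per_locus |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      total_alleles = sum(.data$n_alleles),
      mean_alleles_per_locus = mean(.data$n_alleles),
      mean_gene_diversity = mean(.data$gene_diversity, na.rm = TRUE),
      mean_pic = mean(.data$pic, na.rm = TRUE),
      .groups = "drop"
    )
  list(per_locus = per_locus, summary = summary)
}
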