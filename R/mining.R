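# ---- per-allele phenotypic effects and favorable-allele mining --------------

#' Phenotypic effect of one allele
#'
#' The allele-effect statistic compares carriers with the whole panel:
#' \deqn{a_i = \frac{1}{n_i}\sum_j x_{ij} - \frac{N_k}{n_k}}
#' where \eqn{x_{ij}} are the trait values (across-environment line means) of
#' the \eqn{n_i} accessions carrying allele i, \eqn{N_k} the summed value over
#' all phenotyped accessions and \eqn{n_k} their number. Positive
#' \eqn{a_i} means carriers exceed the panel mean. Accessions with a missing
#' call are excluded from the carrier mean but still contribute to the
#' overall mean when phenotyped.
#'
#' @param lm_across Across-environment line means (tibble `accession_id`,
#'   `trait`, `value`), e.g. from [line_means()].
#' @param panel A [genotype_panel()].
#' @param marker,allele Marker id and integer allele code.
#' @param trait Trait name.
#' @return A one-row tibble `(marker_id, allele, trait, a_i, n_carriers,
#'   n_total, overall_mean)`; `a_i` is `NA` with a warning when no carrier is
#'   phenotyped.
#' @export
allele_effect <- function(lm_across, panel, marker, allele, trait) {
  stopifnot(inherits(panel, "genotype_panel"))
  ph <- dplyr::filter(lm_across, .data$trait == !!trait, !is.na(.data$value))
  ph <- ph[ph$accession_id %in% rownames(panel$calls), ]
  if (nrow(ph) == 0L) abort(paste0("no phenotyped accessions for trait '", trait, "'"))
  overall <- mean(ph$value)
  calls <- panel$calls[ph$accession_id, marker]
  carriers <- ph$value[!is.na(calls) & calls == allele]
  if (length(carriers) == 0L) {
    warn(paste0("no phenotyped carrier of ", marker, "-", allele,
                "; effect is NA"))
    ai <- NA_real_
  } else {
    ai <- mean(carriers) - overall
  }
  tibble::tibble(marker_id = marker, allele = as.integer(allele),
                 trait = trait, a_i = ai,
                 n_carriers = length(carriers), n_total = nrow(ph),
                 overall_mean = overall)
}

#' Allele effects for a set of marker-trait pairs
#'
#' Computes [allele_effect()] for every allele of every requested
#' marker-trait pair, flags favorable alleles against the breeding
#' objectives, and attaches the top representative carriers.
#'
#' @param lm_across Across-environment line means.
#' @param panel A [genotype_panel()].
#' @param marker_traits Tibble `(marker_id, trait)` of pairs to score --
#'   typically the stable associations of an [association_summary()].
#' @param objectives Named vector of objective directions per trait (+1 =
#'   maximise, -1 = minimise); defaults to the lint-yield convention (all +1
#'   except seed index). Every scored trait must have one.
#' @param min_carriers Drop alleles with fewer phenotyped carriers (default
#'   0, i.e. no minimum).
#' @param top_n Representative accessions to record per allele.
#' @return A tibble with one row per marker-allele-trait: effect statistics,
#'   `favorable`, and `representatives` (comma-joined accession ids).
#' @export
allele_effects <- function(lm_across, panel, marker_traits,
                           objectives = DEFAULT_OBJECTIVES,
                           min_carriers = 0L, top_n = 3L) {
  stopifnot(inherits(panel, "genotype_panel"))
  marker_traits <- dplyr::distinct(
    tibble::as_tibble(marker_traits)[, c("marker_id", "trait")])
  out <- purrr::pmap_dfr(marker_traits, function(marker_id, trait) {
    calls <- panel$calls[, marker_id]
    alleles <- sort(unique(calls[!is.na(calls)]))
    purrr::map_dfr(alleles, function(a) {
      eff <- suppressWarnings(
        allele_effect(lm_across, panel, marker_id, a, trait))
      eff$representatives <- paste(
        representative_accessions(lm_across, panel, marker_id, a, trait,
                                  objectives = objectives, top_n = top_n),
        collapse = ", ")
      eff
    })
  })
  out <- dplyr::filter(out, .data$n_carriers >= min_carriers)
  favorable_alleles(out, objectives)
}

#' Flag favorable alleles
#'
#' An allele is favorable when the sign of its effect matches the trait's
#' breeding-objective direction: a positive effect for a trait to maximise,
#' a negative effect for a trait to minimise. A zero or missing effect is
#' never favorable.
#'
#' @param effects Tibble with columns `trait` and `a_i` (e.g. from
#'   [allele_effects()]).
#' @param objectives Named direction vector (+1/-1) covering every trait.
#' @return `effects` with a logical `favorable` column.
#' @export
favorable_alleles <- function(effects, objectives = DEFAULT_OBJECTIVES) {
  missing_obj <- setdiff(unique(effects$trait), names(objectives))
  if (length(missing_obj) > 0) {
    abort(paste0("no breeding objective for trait(s): ",
                 paste(missing_obj, collapse = ", ")))
  }
  dplyr::mutate(effects,
                favorable = !is.na(.data$a_i) &
                  sign(.data$a_i) == unname(objectives[.data$trait]) &
                  .data$a_i != 0)
}

#' Representative accessions for an allele
#'
#' The top carriers of an allele ranked by trait value in the objective
#' direction (largest first for traits to maximise, smallest first
#' otherwise); ties are broken by accession id in lexicographic order.
#'
#' @inheritParams allele_effect
#' @param objectives Named direction vector (+1/-1).
#' @param top_n How many accessions to return (fewer if fewer carriers).
#' @return Character vector of accession ids.
#' @export
representative_accessions <- function(lm_across, panel, marker, allele, trait,
                                      objectives = DEFAULT_OBJECTIVES,
                                      top_n = 3L) {
  dir <- unname(objectives[trait])
  if (is.na(dir)) abort(paste0("no breeding objective for trait '", trait, "'"))
  ph <- dplyr::filter(lm_across, .data$trait == !!trait, !is.na(.data$value))
  ph <- ph[ph$accession_id %in% rownames(panel$calls), ]
  calls <- panel$calls[ph$accession_id, marker]
  carriers <- ph[!is.na(calls) & calls == allele, ]
  if (nrow(carriers) == 0L) return(character(0))
  ord <- order(dir * -carriers$value, carriers$accession_id)
  carriers$accession_id[ord][seq_len(min(top_n, nrow(carriers)))]
}

#' Classify founder-to-modern allele transmission
#'
#' Given an allele's frequency in the founder (CK) group and in each
#' historically released era group, assigns one of three transmission
#' classes: 1 = present in the founders and at high frequency in every era
#' group (passed down stably and nearly fixed); 2 = present in the founders
#' but at moderate-to-low frequency somewhere (underutilised); 3 = absent
#' from the founders (novel variation from other parents, mutation or
#' recombination).
#'
#' @param ck_freq Allele frequency in the founder group.
#' @param group_freqs Numeric vector of per-era frequencies (groups I-VI).
#' @param high_freq_threshold Minimum per-group frequency for class 1
#'   (default 0.8).
#' @return Integer class (1, 2 or 3).
#' @export
classify_transmission <- function(ck_freq, group_freqs,
                                  high_freq_threshold = 0.8) {
  if (any(c(ck_freq, group_freqs) < 0 | c(ck_freq, group_freqs) > 1,
          na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]")
  }
  if (is.na(ck_freq)) abort("founder-group frequency is required")
  if (ck_freq == 0) return(3L)
  if (all(group_freqs >= high_freq_threshold, na.rm = TRUE)) return(1L)
  2L
}

#' Era-group frequency table with transmission classes
#'
#' For each allele of interest, computes its frequency over typed lines in
#' the founder (CK) group and each era group, plus the whole-panel total,
#' and classifies its transmission with [classify_transmission()].
#'
#' @param panel A [genotype_panel()] whose metadata (or `meta`) defines
#'   `era_group`; the CK group must be non-empty.
#' @param alleles Tibble `(marker_id, allele)` of alleles to track, e.g. the
#'   favorable alleles of [allele_effects()].
#' @param meta Optional metadata tibble overriding `panel$meta`.
#' @param high_freq_threshold Class-1 boundary passed to the classifier.
#' @return A tibble: `marker_id`, `allele`, one frequency column per era
#'   group present, `Total`, `transmission_class`.
#' @export
transmission_table <- function(panel, alleles, meta = NULL,
                               high_freq_threshold = 0.8) {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- tibble::as_tibble(meta %||% panel$meta)
  if (is.null(meta) || nrow(meta) == 0L) abort("accession metadata required")
  meta$era_group <- factor(as.character(meta$era_group), levels = ERA_LEVELS)
  groups_present <- intersect(ERA_LEVELS,
                              unique(as.character(meta$era_group)))
  if (!"CK" %in% groups_present) abort("the CK (founder) group is empty")
  era_groups <- setdiff(groups_present, c("CK", "other"))
  alleles <- dplyr::distinct(tibble::as_tibble(alleles)[, c("marker_id",
                                                            "allele")])
  purrr::pmap_dfr(alleles, function(marker_id, allele) {
    if (!marker_id %in% colnames(panel$calls)) {
      abort(paste0("marker '", marker_id, "' not in panel"))
    }
    calls <- panel$calls[, marker_id]
    if (!allele %in% calls) {
      abort(paste0("allele ", marker_id, "-", allele, " absent from panel"))
    }
    freq_in <- function(ids) {
      x <- calls[ids]
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(NA_real_)
      mean(x == allele)
    }
    by_group <- vapply(groups_present, function(g) {
      freq_in(meta$accession_id[as.character(meta$era_group) == g])
    }, numeric(1))
    total <- freq_in(meta$accession_id)
    cls <- classify_transmission(by_group[["CK"]],
                                 by_group[era_groups],
                                 high_freq_threshold)
    dplyr::bind_cols(
      tibble::tibble(marker_id = marker_id, allele = as.integer(allele)),
      tibble::as_tibble(as.list(by_group)),
      tibble::tibble(Total = total, transmission_class = cls)
    )
  })
}
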