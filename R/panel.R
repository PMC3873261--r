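#' Construct a genotype panel
#'
#' Bundles an accessions-by-markers matrix of allele codes with a genetic map
#' and (optionally) accession metadata. Accessions are inbred, effectively
#' homozygous lines, so each cell holds a single small positive integer allele
#' code (or `NA` for missing). Allele codes are locus-local labels: code 2 at
#' one locus is unrelated to code 2 at another.
#'
#' @param calls Integer matrix, rows = accessions (rownames = accession ids),
#'   columns = markers (colnames = marker ids). `NA` marks missing calls.
#' @param map Data frame with columns `marker_id`, `chromosome`,
#'   `position_cM`; must cover every marker column in `calls`. Markers on the
#'   same chromosome are "linked", on different chromosomes "unlinked".
#' @param meta Optional data frame of accession metadata with columns
#'   `accession_id`, `era_group` (one of CK, I--VI, other), `region`,
#'   `is_founder`. The CK group is the founder (check) group, so `era_group ==
#'   "CK"` requires `is_founder = TRUE`.
#' @return An object of class `genotype_panel`: a list with elements `calls`,
#'   `map` (tibble), and `meta` (tibble or `NULL`).
#' @export
genotype_panel <- function(calls, map, meta = NULL) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix of allele codes")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must carry accession rownames and marker colnames")
  }
  if (anyDuplicated(rownames(calls))) abort("duplicate accession ids in `calls`")
  if (anyDuplicated(colnames(calls))) abort("duplicate marker ids in `calls`")
  storage.mode(calls) <- "integer"
  ok <- is.na(calls) | calls >= 1L
  if (!all(ok)) abort("allele codes must be positive integers (>= 1) or NA")

  map <- tibble::as_tibble(map)
  req <- c("marker_id", "chromosome", "position_cM")
  if (!all(req %in% names(map))) {
    abort("`map` needs columns marker_id, chromosome, position_cM")
  }
  if (anyDuplicated(map$marker_id)) abort("duplicate marker ids in `map`")
  if (!all(is.finite(map$position_cM)) || any(map$position_cM < 0)) {
    abort("map positions must be finite and non-negative (cM)")
  }
  missing_from_map <- setdiff(colnames(calls), map$marker_id)
  if (length(missing_from_map) > 0) {
    abort(paste0("markers absent from map: ",
                 paste(head(missing_from_map, 5), collapse = ", ")))
  }
  map <- map[match(colnames(calls), map$marker_id), , drop = FALSE]

  if (!is.null(meta)) {
    meta <- validate_accession_meta(meta, rownames(calls))
  }
  structure(list(calls = calls, map = map, meta = meta),
            class = "genotype_panel")
}

validate_accession_meta <- function(meta, accession_ids = NULL) {
  meta <- tibble::as_tibble(meta)
  req <- c("accession_id", "era_group", "region", "is_founder")
  if (!all(req %in% names(meta))) {
    abort("metadata needs columns accession_id, era_group, region, is_founder")
  }
  if (anyDuplicated(meta$accession_id)) abort("duplicate accession ids in metadata")
  bad <- setdiff(unique(as.character(meta$era_group)), ERA_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown era_group label(s): ", paste(bad, collapse = ", ")))
  }
  meta$era_group <- factor(as.character(meta$era_group), levels = ERA_LEVELS)
  if (any(meta$era_group == "CK" & !meta$is_founder)) {
    abort("accessions in the CK group must have is_founder = TRUE")
  }
  if (!is.null(accession_ids)) {
    unknown <- setdiff(meta$accession_id, accession_ids)
    if (length(unknown) > 0) {
      abort(paste0("metadata rows for accessions absent from panel: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  meta
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$calls), " accessions x ",
      ncol(x$calls), " markers on ",
      length(unique(x$map$chromosome)), " chromosomes\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing calls: ", sprintf("%.2f%%", 100 * miss),
      if (!is.null(x$meta)) "; metadata attached" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

n_accessions <- function(panel) nrow(panel$calls)
n_markers <- function(panel) ncol(panel$calls)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param accessions,markers Character vectors of ids to keep (default: all).
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, accessions = NULL, markers = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  acc <- accessions %||% rownames(panel$calls)
  mk <- markers %||% colnames(panel$calls)
  missing_acc <- setdiff(acc, rownames(panel$calls))
  if (length(missing_acc)) abort("unknown accession id(s) in subset")
  missing_mk <- setdiff(mk, colnames(panel$calls))
  if (length(missing_mk)) abort("unknown marker id(s) in subset")
  meta <- panel$meta
  if (!is.null(meta)) meta <- meta[meta$accession_id %in% acc, , drop = FALSE]
  genotype_panel(panel$calls[acc, mk, drop = FALSE],
                 panel$map[panel$map$marker_id %in% mk, , drop = FALSE],
                 meta)
}

#' Tidy a genotype panel into long format
#'
#' @param x A [genotype_panel()].
#' @param ... Unused.
#' @return A tibble with columns `accession_id`, `marker_id`, `allele`
#'   (integer code, `NA` when missing).
#' @export
tidy.genotype_panel <- function(x, ...) {
  tibble::tibble(
    accession_id = rep(rownames(x$calls), times = ncol(x$calls)),
    marker_id = rep(colnames(x$calls), each = nrow(x$calls)),
    allele = as.integer(x$calls)
  )
}

#' @export
glance.genotype_panel <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x$calls),
    n_markers = ncol(x$calls),
    n_chromosomes = length(unique(x$map$chromosome)),
    missing_rate = mean(is.na(x$calls))
  )
}
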