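#' Read a genotype matrix
#'
#' Reads a delimited table of allele codes: one row per accession, one column
#' per marker, header row of marker ids, first column the accession id.
#' Cells equal to `missing_token` become `NA`; any other non-integer cell is a
#' format error. Allele codes are preserved exactly.
#'
#' @param path Path to a TSV/CSV file.
#' @param map A genetic map (data frame `marker_id`, `chromosome`,
#'   `position_cM`) or a path readable by [read_genetic_map()].
#' @param missing_token String marking missing calls (default `"NA"`).
#' @param delim Field delimiter, `"\t"` by default.
#' @param meta Optional accession metadata (data frame or path for
#'   [read_accession_meta()]).
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, map, missing_token = "NA", delim = "\t",
                           meta = NULL) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE,
  name_repair = "minimal")
  if (ncol(raw) < 2) abort("genotype table needs an id column plus >= 1 marker")
  marker_ids <- names(raw)[-1]
  if (anyDuplicated(marker_ids)) abort("duplicated marker column name(s)")
  acc <- raw[[1]]
  if (anyDuplicated(acc)) abort("duplicated accession id(s)")
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == missing_token] <- NA_character_
  parsed <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- !is.na(cells) & (is.na(parsed) | parsed != round(parsed) | parsed < 1)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    abort(paste0("unparseable allele code '", cells[bad][1], "' at accession '",
                 acc[i[1]], "', marker '", marker_ids[i[2]],
                 "' (integer >= 1 or missing token expected)"))
  }
  calls <- matrix(as.integer(parsed), nrow = length(acc),
                  dimnames = list(acc, marker_ids))
  if (is.character(map) && length(map) == 1L) map <- read_genetic_map(map)
  if (is.character(meta) && length(meta) == 1L) meta <- read_accession_meta(meta)
  genotype_panel(calls, map, meta)
}

#' Read a genetic map
#'
#' Three-column delimited file: marker id, chromosome, position in cM.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble with columns `marker_id`, `chromosome`, `position_cM`.
#' @export
read_genetic_map <- function(path, delim = "\t") {
  map <- readr::read_delim(path, delim = delim, col_types = "ccd",
                           progress = FALSE, show_col_types = FALSE)
  names(map) <- c("marker_id", "chromosome", "position_cM")
  if (anyDuplicated(map$marker_id)) abort("duplicate marker ids in map file")
  map
}

#' Read a long-format phenotype table
#'
#' Columns: `accession_id`, `environment_id`, `replicate_id`, `trait`,
#' `value`. One row per observation; (accession, environment, replicate,
#' trait) must be unique.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble of phenotype records.
#' @export
read_phenotypes <- function(path, delim = "\t") {
  ph <- readr::read_delim(path, delim = delim, col_types = "ccccd",
                          progress = FALSE, show_col_types = FALSE)
  names(ph) <- c("accession_id", "environment_id", "replicate_id", "trait",
                 "value")
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  ph <- tibble::as_tibble(ph)
  req <- c("accession_id", "environment_id", "replicate_id", "trait", "value")
  if (!all(req %in% names(ph))) {
    abort("phenotypes need columns accession_id, environment_id, replicate_id, trait, value")
  }
  if (any(!is.na(ph$value) & !is.finite(ph$value))) {
    abort("phenotype values must be finite or missing")
  }
  key <- paste(ph$accession_id, ph$environment_id, ph$replicate_id, ph$trait)
  if (anyDuplicated(key)) {
    abort("duplicate (accession, environment, replicate, trait) record(s)")
  }
  ph
}

#' Read accession metadata
#'
#' Delimited file with columns `accession_id`, `era_group` (CK, I--VI or
#' other), `region`, `is_founder` (logical).
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A validated tibble of metadata.
#' @export
read_accession_meta <- function(path, delim = "\t") {
  meta <- readr::read_delim(path, delim = delim, col_types = "cccl",
                            progress = FALSE, show_col_types = FALSE)
  names(meta) <- c("accession_id", "era_group", "region", "is_founder")
  validate_accession_meta(meta)
}

#' Write panel artifacts as delimited text
#'
#' `write_genotypes()` writes the allele-code matrix in the dialect
#' [read_genotypes()] consumes; the other writers mirror their readers.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @param missing_token Token written for missing calls.
#' @param delim Field delimiter.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(panel, path, missing_token = "NA", delim = "\t") {
  df <- tibble::as_tibble(panel$calls, rownames = "accession_id")
  df <- dplyr::mutate(df, dplyr::across(-"accession_id",
                                        ~ ifelse(is.na(.x), missing_token,
                                                 as.character(.x))))
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' @rdname write_genotypes
#' @param map A genetic map tibble.
#' @export
write_genetic_map <- function(map, path, delim = "\t") {
  readr::write_delim(map, path, delim = delim)
  invisible(path)
}

#' @rdname write_genotypes
#' @param pheno A phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path, delim = "\t") {
  readr::write_delim(pheno, path, delim = delim)
  invisible(path)
}

#' @rdname write_genotypes
#' @param meta An accession metadata tibble.
#' @export
write_accession_meta <- function(meta, path, delim = "\t") {
  meta <- dplyr::mutate(meta, era_group = as.character(.data$era_group))
  readr::write_delim(meta, path, delim = delim)
  invisible(path)
}

#' Drop markers with excessive missing data
#'
#' Removes every marker whose missing-call fraction strictly exceeds
#' `max_missing_rate` (the conventional screen drops markers with more than
#' 10% missing data). Survivor order is preserved and each removal is logged
#' via [message()].
#'
#' @param panel A [genotype_panel()].
#' @param max_missing_rate Maximum tolerated missing fraction in `[0, 1]`.
#' @return The filtered `genotype_panel`.
#' @export
filter_markers <- function(panel, max_missing_rate = 0.10) {
  stopifnot(inherits(panel, "genotype_panel"))
  assert_proportion(max_missing_rate, "max_missing_rate")
  miss <- colMeans(is.na(panel$calls))
  drop <- miss > max_missing_rate
  if (all(drop)) {
    abort("all markers exceed the missing-data threshold; empty panel refused")
  }
  for (m in colnames(panel$calls)[drop]) {
    inform(sprintf("filter_markers: dropping %s (missing rate %.3f > %.3f)",
                   m, miss[[m]], max_missing_rate))
  }
  if (!any(drop)) return(panel)
  subset_panel(panel, markers = colnames(panel$calls)[!drop])
}

#' Line means of phenotype records
#'
#' Averages replicate observations per accession within each environment, or
#' averages the per-environment means across environments (unweighted; cells
#' with no data stay missing). Across-environment means on unbalanced data
#' (accessions missing whole environments) are tolerated with a warning and
#' carry the number of contributing environments in `n_env`.
#'
#' @param pheno Long-format phenotype tibble (see [read_phenotypes()]).
#' @param level `"per_environment"` or `"across_environments"`.
#' @param traits Optional character vector restricting the traits; unknown
#'   trait names are an error.
#' @return A tibble `(accession_id, [environment_id], trait, value[, n_env])`.
#' @export
line_means <- function(pheno, level = c("per_environment",
                                        "across_environments"),
                       traits = NULL) {
  level <- match.arg(level)
  pheno <- validate_phenotypes(pheno)
  if (!is.null(traits)) {
    unknown <- setdiff(traits, unique(pheno$trait))
    if (length(unknown)) {
      abort(paste0("unknown trait name(s): ", paste(unknown, collapse = ", ")))
    }
    pheno <- dplyr::filter(pheno, .data$trait %in% traits)
  }
  per_env <- pheno |>
    dplyr::group_by(.data$accession_id, .data$environment_id, .data$trait) |>
    dplyr::summarise(value = if (all(is.na(.data$value))) NA_real_
                     else mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (level == "per_environment") return(per_env)
  n_total_env <- length(unique(pheno$environment_id))
  out <- per_env |>
    dplyr::group_by(.data$accession_id, .data$trait) |>
    dplyr::summarise(n_env = sum(!is.na(.data$value)),
                     value = if (all(is.na(.data$value))) NA_real_
                     else mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::relocate("value", .before = "n_env")
  if (any(out$n_env < n_total_env)) {
    warn("across-environment means computed on unbalanced data; see `n_env`")
  }
  out
}
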