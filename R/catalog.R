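# Isolate catalog: data model and I/O for a culturable-isolate survey table,
# plus genus-level abundance tabulation per (plant, tissue) stratum.

TISSUES <- c("root", "stem", "leaf", "tuber")
PLANT_CODES <- c(P_ternata = "PT", P_pedatisecta = "PP")

CATALOG_COLUMNS <- c("strain_code", "plant", "tissue", "closest_match",
                     "match_accession", "coverage_pct", "identity_pct",
                     "own_accession")

#' Extract the genus from a binomial
#'
#' The genus is the first whitespace-delimited token of the closest-match
#' binomial; trailing qualifiers such as `"sp."` are dropped with the rest of
#' the name. Leading/trailing whitespace is ignored.
#'
#' @param binomial character vector of binomials, e.g. `"Fusarium sp."`.
#' @return character vector of genus names.
#' @examples
#' genus_of("Fusarium sp.")               # "Fusarium"
#' genus_of("Alternaria angustiovoidea")  # "Alternaria"
#' @export
genus_of <- function(binomial) {
  if (!is.character(binomial) || length(binomial) == 0)
    stop_validation("'binomial' must be a non-empty character vector")
  trimmed <- trimws(binomial)
  if (any(is.na(trimmed)) || any(!nzchar(trimmed)))
    stop_validation("empty or whitespace-only binomial")
  vapply(strsplit(trimmed, "\\s+"), `[[`, character(1), 1L)
}

validate_catalog_records <- function(records) {
  missing <- setdiff(CATALOG_COLUMNS, names(records))
  if (length(missing) > 0)
    stop_validation("catalog is missing required column(s): %s",
                    paste(missing, collapse = ", "))
  if (anyDuplicated(records$strain_code))
    stop_validation("duplicate strain_code: %s",
                    paste(unique(records$strain_code[duplicated(records$strain_code)]),
                          collapse = ", "))
  bad_tissue <- setdiff(unique(records$tissue), TISSUES)
  if (length(bad_tissue) > 0)
    stop_validation("unknown tissue value(s): %s (expected %s)",
                    paste(bad_tissue, collapse = ", "),
                    paste(TISSUES, collapse = "/"))
  bad_plant <- setdiff(unique(records$plant), names(PLANT_CODES))
  if (length(bad_plant) > 0)
    stop_validation("unknown plant value(s): %s", paste(bad_plant, collapse = ", "))
  for (col in c("coverage_pct", "identity_pct")) {
    v <- records[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop_validation("%s outside [0, 100]", col)
  }
  invisible(records)
}

#' Construct an isolate catalog
#'
#' @param records data frame with the catalog schema columns (see
#'   [read_catalog()]); a `genus` column is derived from `closest_match`.
#' @param provenance free-text description of where the table came from.
#' @return an `isolate_catalog`: the validated data frame with a
#'   `provenance` attribute.
#' @export
isolate_catalog <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0) {
    validate_catalog_records(records)
    records$genus <- genus_of(records$closest_match)
  } else {
    for (col in c(CATALOG_COLUMNS, "genus"))
      if (is.null(records[[col]])) records[[col]] <- character(0)
  }
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("isolate_catalog", "data.frame"))
}

#' Read an isolate catalog from TSV/CSV
#'
#' Expects a header row naming the schema columns `strain_code`, `plant`
#' (encoded `"PT"`/`"PP"` or spelled out), `tissue` (root/stem/leaf/tuber),
#' `closest_match`, `match_accession`, `coverage_pct`, `identity_pct`,
#' `own_accession`. The packaged survey table is available via
#' `system.file("extdata", "pinellia_isolates.tsv", package = "endodiv")`.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return an [isolate_catalog()].
#' @export
read_catalog <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("catalog file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           check.names = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing) > 0)
    stop_validation("catalog is missing required column(s): %s",
                    paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("catalog file has a header but no data rows: ", path)
    return(isolate_catalog(raw[, CATALOG_COLUMNS], provenance = path))
  }
  # accept either the two-letter plant codes or the full labels
  code_map <- stats::setNames(names(PLANT_CODES), PLANT_CODES)
  plant <- raw$plant
  coded <- plant %in% names(code_map)
  plant[coded] <- code_map[plant[coded]]
  raw$plant <- plant
  raw$coverage_pct <- as.numeric(raw$coverage_pct)
  raw$identity_pct <- as.numeric(raw$identity_pct)
  isolate_catalog(raw[, CATALOG_COLUMNS], provenance = path)
}

#' Write an isolate catalog back to TSV/CSV
#'
#' Inverse of [read_catalog()]: plants are re-encoded as `"PT"`/`"PP"` and a
#' written file read back yields an identical catalog.
#'
#' @param catalog an [isolate_catalog()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_catalog <- function(catalog, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(catalog, "isolate_catalog"))
  out <- as.data.frame(catalog)[, CATALOG_COLUMNS, drop = FALSE]
  out$plant <- PLANT_CODES[out$plant]
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged Pinellia survey catalog
#'
#' Convenience loader for the transcribed isolate table of the
#' *P. ternata* / *P. pedatisecta* survey (77 records).
#'
#' @return an [isolate_catalog()] of 77 records.
#' @export
pinellia_catalog <- function() {
  read_catalog(system.file("extdata", "pinellia_isolates.tsv",
                           package = "endodiv", mustWork = TRUE))
}

#' Tabulate genus abundances within a stratum
#'
#' Counts isolates per genus within the subset selected by the optional
#' `plant` and `tissue` filters. Genera are ordered lexicographically so the
#' tabulation is deterministic.
#'
#' @param catalog an [isolate_catalog()].
#' @param plant optional `"P_ternata"` or `"P_pedatisecta"`.
#' @param tissue optional tissue (`"root"`, `"stem"`, `"leaf"`, `"tuber"`).
#' @return an `abundance_vector`: list with `stratum`, `counts` (named
#'   integer vector, genus -> Ni), `Nt` (total isolates), `S` (genera
#'   observed) and `Pi` (relative abundances).
#' @export
tabulate_abundance <- function(catalog, plant = NULL, tissue = NULL) {
  stopifnot(inherits(catalog, "isolate_catalog"))
  if (!is.null(plant) && !plant %in% names(PLANT_CODES))
    stop_validation("unknown plant filter: %s", plant)
  if (!is.null(tissue) && !tissue %in% TISSUES)
    stop_validation("unknown tissue filter: %s", tissue)
  keep <- rep(TRUE, nrow(catalog))
  if (!is.null(plant)) keep <- keep & catalog$plant == plant
  if (!is.null(tissue)) keep <- keep & catalog$tissue == tissue
  genera <- catalog$genus[keep]
  if (length(genera) == 0)
    stop_validation("empty stratum (plant=%s, tissue=%s): diversity indices are undefined for Nt = 0",
                    plant %||% "all", tissue %||% "all")
  counts <- table(genera)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  abundance_vector(counts,
                   stratum = list(plant = plant %||% "all",
                                  tissue = tissue %||% "all"))
}

#' Construct an abundance vector
#'
#' @param counts named positive integer vector, genus -> isolate count.
#' @param stratum list describing the stratum (plant, tissue) or `"all"`.
#' @return an `abundance_vector`.
#' @export
abundance_vector <- function(counts, stratum = list(plant = "all", tissue = "all")) {
  if (length(counts) == 0) stop_validation("empty abundance vector")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_validation("abundance counts must be named by genus")
  if (any(counts != round(counts)) || any(counts < 1))
    stop_validation("abundance counts must be positive integers (zero-count genera are not admitted)")
  counts <- stats::setNames(as.integer(counts), names(counts))
  Nt <- sum(counts)
  structure(list(stratum = stratum, counts = counts, Nt = Nt,
                 S = length(counts), Pi = counts / Nt),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("Abundance vector (%s / %s): Nt = %d, S = %d\n",
              x$stratum$plant, x$stratum$tissue, x$Nt, x$S))
  print(x$counts)
  invisible(x)
}

#' Survey-level summary counts
#'
#' Totals per plant, per tissue (pooled over plants), the per-plant-by-tissue
#' grid, distinct genera per tissue and overall.
#'
#' @param catalog an [isolate_catalog()].
#' @return a `catalog_summary` list: `n_isolates`, `per_plant`, `per_tissue`,
#'   `per_plant_tissue` (matrix), `genera_per_tissue`, `n_genera`, `genera`.
#' @export
summary_counts <- function(catalog) {
  stopifnot(inherits(catalog, "isolate_catalog"))
  tissue <- factor(catalog$tissue, levels = TISSUES)
  plant <- factor(catalog$plant, levels = names(PLANT_CODES))
  per_tissue <- stats::setNames(as.integer(table(tissue)), TISSUES)
  per_plant <- stats::setNames(as.integer(table(plant)), names(PLANT_CODES))
  grid <- table(plant, tissue)
  genera_per_tissue <- vapply(TISSUES, function(tt)
    length(unique(catalog$genus[catalog$tissue == tt])), integer(1))
  structure(list(
    n_isolates = nrow(catalog),
    per_plant = per_plant,
    per_tissue = per_tissue,
    per_plant_tissue = unclass(grid),
    genera_per_tissue = genera_per_tissue,
    n_genera = length(unique(catalog$genus)),
    genera = sort(unique(catalog$genus))
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("Isolate survey: %d isolates, %d genera\n", x$n_isolates, x$n_genera))
  cat("Per plant:  "); print(x$per_plant)
  cat("Per tissue: "); print(x$per_tissue)
  invisible(x)
}
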