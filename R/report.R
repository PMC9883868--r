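# One-shot report runner: reads the catalog, phytotoxicity and (optionally)
# alignment inputs, and writes the diversity grid, band counts, Newick tree
# and a summary. Payload files are deterministic under a fixed config and
# seed; timestamps live only in a sidecar metadata file so payloads are
# byte-comparable across reruns.

#' Build a run configuration
#'
#' @param catalog_path isolate catalog TSV.
#' @param phyto_path phytotoxicity screen TSV.
#' @param alignment_path optional aligned FASTA for the phylogeny stage.
#' @param zones_path optional IZD/MIC screen TSV.
#' @param out_dir output directory (created if absent).
#' @param digits report rounding digits (>= 0, default 4).
#' @param bootstrap bootstrap replicates (>= 1, default 100).
#' @param model distance model for the phylogeny stage.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(catalog_path, phyto_path, alignment_path = NULL,
                       zones_path = NULL, out_dir, digits = 4,
                       bootstrap = 100, model = "p", seed = 1) {
  if (digits < 0) stop_validation("digits must be >= 0")
  if (bootstrap < 1) stop_validation("bootstrap replicates must be >= 1")
  structure(list(catalog_path = catalog_path, phyto_path = phyto_path,
                 alignment_path = alignment_path, zones_path = zones_path,
                 out_dir = out_dir, digits = digits, bootstrap = bootstrap,
                 model = model, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  fnv1a_hash(paste(names(flat), flat, sep = "=", collapse = ";"))
}

#' Run the full survey analysis and write a report bundle
#'
#' Validates all inputs up front (no partial output on a missing file), then
#' writes into `config$out_dir`:
#' \describe{
#'   \item{diversity.tsv}{the per-stratum index grid, indices as rows.}
#'   \item{diversity_discrepancies.tsv}{computed-vs-reported cells that
#'     disagree (only when a reported reference applies).}
#'   \item{summary.json}{catalog headline counts.}
#'   \item{bands.json}{phytotoxicity band counts and the over-50% count.}
#'   \item{tree.nwk}{bootstrap-annotated NJ tree (when an alignment is given).}
#'   \item{run_metadata.json}{tool version, config hash, timestamp.}
#' }
#'
#' @param config a [run_config()].
#' @param reported optional long-format reference grid for discrepancy
#'   screening (default: the packaged survey's reported values when the
#'   packaged catalog is being analysed, else `NULL`).
#' @return invisibly, a list with the computed objects and written paths.
#' @export
run_all <- function(config, reported = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(catalog = config$catalog_path, phyto = config$phyto_path,
              alignment = config$alignment_path, zones = config$zones_path)
  missing <- inputs[!vapply(inputs, file.exists, logical(1))]
  if (length(missing) > 0)
    stop_validation("input file(s) not found: %s",
                    paste(sprintf("%s (%s)", missing, names(missing)),
                          collapse = ", "))

  catalog <- read_catalog(config$catalog_path)
  phyto <- read_phytotoxicity(config$phyto_path)
  if (is.null(reported) &&
      normalizePath(config$catalog_path) ==
        normalizePath(system.file("extdata", "pinellia_isolates.tsv",
                                  package = "endodiv")))
    reported <- reported_diversity()

  tbl <- diversity_table(catalog)
  counts <- summary_counts(catalog)
  bands <- classify_bands(phyto)
  over50 <- count_over(phyto, 50, strict = TRUE)
  tree <- NULL
  if (!is.null(config$alignment_path)) {
    aln <- read_fasta(config$alignment_path)
    tree <- bootstrap_support(aln, replicates = config$bootstrap,
                              seed = config$seed, model = config$model)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  grid <- format_diversity_table(tbl, config$digits)
  paths$diversity <- file.path(config$out_dir, "diversity.tsv")
  utils::write.table(cbind(index = rownames(grid), grid), paths$diversity,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(reported)) {
    disc <- flag_index_discrepancies(tbl, reported, digits = config$digits)
    paths$discrepancies <- file.path(config$out_dir,
                                     "diversity_discrepancies.tsv")
    utils::write.table(disc, paths$discrepancies, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(
    n_isolates = counts$n_isolates,
    per_plant = as.list(counts$per_plant),
    per_tissue = as.list(counts$per_tissue),
    genera_per_tissue = as.list(counts$genera_per_tissue),
    n_genera = counts$n_genera
  ), paths$summary, auto_unbox = TRUE, pretty = TRUE)

  paths$bands <- file.path(config$out_dir, "bands.json")
  jsonlite::write_json(c(as.list(bands), list(over_50_strict = over50)),
                       paths$bands, auto_unbox = TRUE, pretty = TRUE)

  if (!is.null(tree)) {
    paths$tree <- file.path(config$out_dir, "tree.nwk")
    write_newick(tree, paths$tree)
  }

  paths$metadata <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(list(
    tool = "endodiv",
    version = as.character(utils::packageVersion("endodiv")),
    config_hash = config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), paths$metadata, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(catalog = catalog, diversity = tbl, summary = counts,
                 bands = bands, over_50 = over50, tree = tree,
                 paths = paths))
}
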