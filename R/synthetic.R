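# Seeded generators for the inputs the analysis assumes: multinomial isolate
# catalogs, truncated-normal radicle assays, and Jukes-Cantor sequence
# evolution along a tree. Every generator draws from a named substream of
# one master seed (see substream_seed), so outputs are bit-reproducible and
# adding a generator never perturbs existing streams.

#' Community specification for catalog simulation
#'
#' @param genus_probabilities named probability vector over genera (sums to
#'   1 within 1e-12).
#' @param n_isolates isolates per stratum.
#' @param plants plants to emit (default both survey plants).
#' @param tissues tissues to emit (default all four).
#' @param seed master seed.
#' @param force_counts if `TRUE`, every stratum receives the exact expected
#'   counts `n_isolates * genus_probabilities` (which must then be whole
#'   numbers) instead of a multinomial draw.
#' @return a `community_spec` list.
#' @export
community_spec <- function(genus_probabilities, n_isolates,
                           plants = names(PLANT_CODES), tissues = TISSUES,
                           seed = 1, force_counts = FALSE) {
  p <- genus_probabilities
  if (length(p) == 0) stop_validation("empty genus probability vector")
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop_validation("genus probabilities must be named")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop_validation("genus probabilities must be nonnegative and sum to 1")
  if (n_isolates < 0) stop_validation("n_isolates must be >= 0")
  if (!all(plants %in% names(PLANT_CODES)))
    stop_validation("unknown plant in spec")
  if (!all(tissues %in% TISSUES)) stop_validation("unknown tissue in spec")
  if (force_counts) {
    expected <- p * n_isolates
    if (any(abs(expected - round(expected)) > 1e-9))
      stop_validation("force_counts requires n_isolates * probabilities to be whole numbers")
  }
  structure(list(genus_probabilities = p, n_isolates = n_isolates,
                 plants = plants, tissues = tissues, seed = seed,
                 force_counts = force_counts),
            class = "community_spec")
}

#' Simulate an isolate catalog
#'
#' Draws genus counts per (plant, tissue) stratum from a multinomial with
#' the spec's probabilities (or forces the expected counts), then emits one
#' synthetic record per isolate with unique strain codes and synthetic
#' accessions.
#'
#' @param spec a [community_spec()].
#' @return an [isolate_catalog()].
#' @export
simulate_catalog <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  p <- spec$genus_probabilities
  rows <- list()
  serial <- 0L
  for (pl in spec$plants) {
    for (tt in spec$tissues) {
      if (spec$n_isolates == 0) next
      if (spec$force_counts) {
        counts <- round(p * spec$n_isolates)
      } else {
        set.seed(substream_seed(spec$seed, paste0("catalog:", pl, ":", tt)))
        counts <- as.vector(stats::rmultinom(1, spec$n_isolates, p))
      }
      genera <- rep(names(p), counts)
      if (length(genera) == 0) next
      idx <- serial + seq_along(genera)
      serial <- serial + length(genera)
      rows[[length(rows) + 1]] <- data.frame(
        strain_code = sprintf("%s%04d", PLANT_CODES[[pl]], idx),
        plant = pl, tissue = tt,
        closest_match = paste(genera, "sp."),
        match_accession = sprintf("SYNREF%04d", match(genera, names(p))),
        coverage_pct = 100, identity_pct = 100,
        own_accession = sprintf("SYN%05d", idx),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(isolate_catalog(data.frame(), provenance = "simulated (empty)"))
  isolate_catalog(do.call(rbind, rows),
                  provenance = sprintf("simulated (seed %s)", spec$seed))
}

#' Radicle assay specification
#'
#' @param control_mean mean control radicle length (mm), > 0.
#' @param control_sd replicate standard deviation (mm).
#' @param effect fractional growth reduction in \[0, 1\].
#' @param replicates replicate count per arm.
#' @param seed master seed.
#' @return an `assay_spec` list.
#' @export
assay_spec <- function(control_mean, control_sd, effect, replicates = 3,
                       seed = 1) {
  if (control_mean <= 0) stop_validation("control_mean must be > 0")
  if (control_sd < 0) stop_validation("control_sd must be >= 0")
  if (effect < 0 || effect > 1) stop_validation("effect must be in [0, 1]")
  if (replicates < 1) stop_validation("replicates must be >= 1")
  structure(list(control_mean = control_mean, control_sd = control_sd,
                 effect = effect, replicates = replicates, seed = seed),
            class = "assay_spec")
}

#' Simulate a radicle-elongation assay
#'
#' Control lengths are Normal(control_mean, control_sd) truncated at zero
#' (negative draws are set to 0, not resampled); treated lengths are
#' Normal(control_mean * (1 - effect), control_sd) truncated likewise. A
#' full effect (`effect = 1`) is complete kill: treated lengths are exactly
#' zero.
#'
#' @param spec an [assay_spec()].
#' @return a [radicle_assay()].
#' @export
simulate_radicle_assay <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  set.seed(substream_seed(spec$seed, "assay:control"))
  control <- pmax(0, stats::rnorm(spec$replicates, spec$control_mean,
                                  spec$control_sd))
  if (spec$effect >= 1) {
    treated <- rep(0, spec$replicates)
  } else {
    set.seed(substream_seed(spec$seed, "assay:treated"))
    treated <- pmax(0, stats::rnorm(spec$replicates,
                                    spec$control_mean * (1 - spec$effect),
                                    spec$control_sd))
  }
  radicle_assay(sprintf("sim_effect_%g", spec$effect), treated, control)
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' The root sequence is i.i.d. uniform over A/C/G/T; along each branch of
#' length `t` (expected substitutions/site) every site changes with
#' probability `3/4 (1 - exp(-4t/3))`, uniformly to one of the other three
#' bases.
#'
#' @param tree a `phylo` with nonnegative branch lengths.
#' @param length number of sites.
#' @param model only `"jc69"`.
#' @param seed master seed.
#' @return a [dna_alignment()] over the tree's tips.
#' @export
evolve_sequences <- function(tree, length, model = "jc69", seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!identical(model, "jc69")) stop_validation("unsupported model: %s", model)
  if (is.null(tree$edge.length))
    stop_validation("tree must have branch lengths")
  if (any(tree$edge.length < 0))
    stop_validation("negative branch length")
  if (length < 1) stop_validation("alignment length must be >= 1")
  bases <- c("A", "C", "G", "T")
  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  root <- nt + 1L
  set.seed(substream_seed(seed, "evolve"))
  seqs <- matrix(NA_integer_, n_nodes, length)
  seqs[root, ] <- sample.int(4, length, replace = TRUE)
  # preorder: parents before children (cladewise edge order)
  pre <- stats::reorder(tree, "cladewise")
  po <- pre$edge
  el <- pre$edge.length
  for (k in seq_len(nrow(po))) {
    pa <- po[k, 1]; ch <- po[k, 2]
    p_change <- 0.75 * (1 - exp(-4 * el[k] / 3))
    x <- seqs[pa, ]
    hit <- stats::runif(length) < p_change
    if (any(hit)) {
      # uniform over the three other bases
      shift <- sample.int(3, sum(hit), replace = TRUE)
      x[hit] <- ((x[hit] - 1 + shift) %% 4) + 1
    }
    seqs[ch, ] <- x
  }
  tipseq <- matrix(bases[seqs[seq_len(nt), , drop = FALSE]], nrow = nt)
  rownames(tipseq) <- tree$tip.label
  dna_alignment(tipseq)
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  lines <- character(0)
  for (i in seq_along(aln$taxa)) {
    lines <- c(lines, paste0(">", aln$taxa[i]),
               paste(aln$seq[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
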