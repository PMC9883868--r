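# Alpha-diversity indices over genus abundance vectors and the per-stratum
# diversity grid. All logarithms are natural: the per-tissue grid of the
# packaged survey reproduces only in nats.

INDEX_NAMES <- c("S", "D_margalef", "H_shannon", "D_simpson", "PIE",
                 "lambda_dominance", "J_pielou")

#' Compute the six diversity indices for one abundance vector
#'
#' For genus counts `Ni` with total `Nt` and relative abundances
#' `Pi = Ni/Nt`:
#' \describe{
#'   \item{Margalef richness}{`D' = (S - 1) / ln(Nt)`}
#'   \item{Shannon-Wiener}{`H' = -sum(Pi * ln(Pi))` (nats)}
#'   \item{Simpson diversity}{`Ds = 1 - sum(Pi^2)`}
#'   \item{Simpson dominance}{`lambda = sum(Pi^2)`}
#'   \item{PIE}{`sum((Ni/Nt) * (Nt - Ni) / (Nt - 1))`, the small-sample
#'     corrected probability that two randomly drawn isolates differ in genus}
#'   \item{Pielou evenness}{`J = H' / ln(S)`}
#' }
#' Degenerate strata yield flagged `NaN` rather than errors: `S = 1` leaves
#' `J` undefined (`ln 1 = 0`), and `Nt = 1` leaves `D'` and `PIE` undefined.
#'
#' @param x an [abundance_vector()] or a named vector of positive counts.
#' @return a `diversity_indices` list: the seven statistics, `Nt`, and a
#'   character vector `flags` drawn from
#'   `c("undefined_J", "undefined_D", "undefined_PIE")`.
#' @examples
#' compute_indices(c(Fusarium = 2, Alternaria = 1, Penicillium = 1))
#' @export
compute_indices <- function(x) {
  if (!inherits(x, "abundance_vector")) x <- abundance_vector(x)
  Ni <- as.numeric(x$counts)
  Nt <- x$Nt
  S <- x$S
  Pi <- Ni / Nt
  flags <- character(0)

  H <- -sum(Pi * log(Pi))
  lambda <- sum(Pi^2)
  Ds <- 1 - lambda

  if (Nt > 1) {
    D_marg <- (S - 1) / log(Nt)
    PIE <- sum((Ni / Nt) * (Nt - Ni) / (Nt - 1))
  } else {
    D_marg <- NaN
    PIE <- NaN
    flags <- c(flags, "undefined_D", "undefined_PIE")
  }
  if (S > 1) {
    J <- H / log(S)
  } else {
    J <- NaN
    flags <- c(flags, "undefined_J")
  }

  structure(list(S = S, Nt = Nt, D_margalef = D_marg, H_shannon = H,
                 D_simpson = Ds, lambda_dominance = lambda, PIE = PIE,
                 J_pielou = J, flags = flags, stratum = x$stratum),
            class = "diversity_indices")
}

#' @export
print.diversity_indices <- function(x, digits = 4, ...) {
  cat(sprintf("Diversity indices (%s / %s), Nt = %d:\n",
              x$stratum$plant %||% "all", x$stratum$tissue %||% "all", x$Nt))
  vals <- c(S = x$S, D_margalef = x$D_margalef, H_shannon = x$H_shannon,
            D_simpson = x$D_simpson, PIE = x$PIE,
            lambda_dominance = x$lambda_dominance, J_pielou = x$J_pielou)
  print(round_half_even(vals, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Diversity grid over all (plant, tissue) strata of a catalog
#'
#' One row per stratum present in the catalog, at genus rank; values are kept
#' at full precision (use [format_diversity_table()] for the 4-decimal
#' presentation). Strata with no isolates are omitted with a warning.
#'
#' @param catalog an [isolate_catalog()].
#' @return data frame with columns `plant`, `tissue`, `Nt`, the seven index
#'   columns, and `flags`.
#' @export
diversity_table <- function(catalog) {
  stopifnot(inherits(catalog, "isolate_catalog"))
  rows <- list()
  for (pl in names(PLANT_CODES)) {
    for (tt in TISSUES) {
      n <- sum(catalog$plant == pl & catalog$tissue == tt)
      if (n == 0) {
        warning(sprintf("stratum (%s, %s) has no isolates; omitted", pl, tt))
        next
      }
      idx <- compute_indices(tabulate_abundance(catalog, plant = pl, tissue = tt))
      rows[[length(rows) + 1]] <- data.frame(
        plant = pl, tissue = tt, Nt = idx$Nt, S = idx$S,
        D_margalef = idx$D_margalef, H_shannon = idx$H_shannon,
        D_simpson = idx$D_simpson, PIE = idx$PIE,
        lambda_dominance = idx$lambda_dominance, J_pielou = idx$J_pielou,
        flags = paste(idx$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Format a diversity grid for reporting
#'
#' Indices as rows and strata as columns, rounded half-to-even.
#'
#' @param tbl output of [diversity_table()].
#' @param digits decimal places (default 4, the survey's presentation).
#' @return a data frame, rownames are index names, one column per stratum
#'   labelled `plant.tissue`.
#' @export
format_diversity_table <- function(tbl, digits = 4) {
  cols <- lapply(seq_len(nrow(tbl)), function(i)
    round_half_even(as.numeric(tbl[i, INDEX_NAMES]), digits))
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- paste(tbl$plant, tbl$tissue, sep = ".")
  rownames(out) <- INDEX_NAMES
  out
}

#' Reported diversity values of the packaged survey
#'
#' Long-format reference grid of the index values reported with the packaged
#' Pinellia survey, for discrepancy screening via [flag_index_discrepancies()].
#'
#' @return data frame with columns `plant`, `tissue`, `index`, `value`.
#' @export
reported_diversity <- function() {
  utils::read.table(system.file("extdata", "pinellia_diversity_reported.tsv",
                                package = "endodiv", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Screen a computed diversity grid against reported values
#'
#' Rounds computed indices to `digits` decimals and compares with a reported
#' reference grid. Cells that disagree are returned rather than patched: a
#' published table can contain values that the stated formulas do not
#' reproduce (the packaged survey has exactly one such cell, the
#' *P. ternata* root Margalef index: reported 2.7906, formula 2.2324).
#'
#' @param tbl output of [diversity_table()].
#' @param reported long-format reference, default [reported_diversity()].
#' @param digits decimals at which to compare (default 4).
#' @return data frame of discrepant cells: `plant`, `tissue`, `index`,
#'   `computed`, `reported`; zero rows when everything matches.
#' @export
flag_index_discrepancies <- function(tbl, reported = reported_diversity(),
                                     digits = 4) {
  out <- list()
  for (k in seq_len(nrow(reported))) {
    r <- reported[k, ]
    row <- tbl[tbl$plant == r$plant & tbl$tissue == r$tissue, ]
    if (nrow(row) != 1 || !r$index %in% names(row)) next
    comp <- round_half_even(row[[r$index]], digits)
    if (!isTRUE(all.equal(comp, r$value, tolerance = 1e-12)))
      out[[length(out) + 1]] <- data.frame(
        plant = r$plant, tissue = r$tissue, index = r$index,
        computed = comp, reported = r$value, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(plant = character(0), tissue = character(0),
                      index = character(0), computed = numeric(0),
                      reported = numeric(0)))
  do.call(rbind, out)
}
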