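# Neighbor-joining phylogenetics, implemented from the agglomeration
# criterion up: pairwise distances (p, JC69, K2P) with pairwise deletion,
# Saitou-Nei joining with a deterministic tie-break, bootstrap supports by
# bipartition matching, and Newick serialisation. Trees are ape "phylo"
# objects so they interoperate with the rest of the R phylogenetics stack.

IUPAC_DNA <- c("A", "C", "G", "T", "U", "N", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an aligned DNA alignment object
#'
#' @param seqs named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = taxa, one base per cell).
#' @return a `dna_alignment`: list with `taxa`, `seq` (character matrix) and
#'   `length` (columns).
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop_validation("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      off <- names(seqs)[lens != lens[1]][1]
      stop_validation("unequal sequence lengths; this reader expects pre-aligned input (offending record: %s)", off)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  taxa <- rownames(m)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop_validation("taxa must be uniquely labelled (duplicate or missing label)")
  bad <- setdiff(unique(as.vector(m)), IUPAC_DNA)
  if (length(bad) > 0)
    stop_validation("non-IUPAC characters in alignment: %s",
                    paste(bad, collapse = ", "))
  structure(list(taxa = taxa, seq = m, length = ncol(m)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa x %d columns\n",
              length(x$taxa), x$length))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Labels are taken up to the first whitespace. Requires at least three
#' records of equal length (the downstream joining step needs >= 3 taxa).
#'
#' @param path FASTA file path.
#' @return a [dna_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("FASTA file not found: %s", path)
  recs <- ape::read.FASTA(path)
  if (length(recs) < 3)
    stop_validation("insufficient taxa: %d record(s), need >= 3", length(recs))
  labels <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(labels))
    stop_validation("duplicate taxon label: %s",
                    labels[duplicated(labels)][1])
  chars <- lapply(as.character(recs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) {
    off <- labels[lens != lens[1]][1]
    stop_validation("unequal sequence lengths; this reader expects pre-aligned input (offending record: %s)", off)
  }
  seqs <- vapply(chars, paste, character(1), collapse = "")
  names(seqs) <- labels
  dna_alignment(seqs)
}

#' Pairwise evolutionary distances with pairwise deletion
#'
#' For each pair, comparable sites are those where both sequences carry an
#' unambiguous base (A/C/G/T after mapping U to T); gaps, N and ambiguity
#' codes are deleted pairwise. Models: `"p"` (mismatch proportion), `"jc69"`
#' (`-3/4 ln(1 - 4p/3)`), `"k2p"` (Kimura 1980 from transition proportion P
#' and transversion proportion Q, `-ln((1-2P-Q) sqrt(1-2Q))/2`).
#'
#' @param aln a [dna_alignment()].
#' @param model `"p"` (default), `"jc69"` or `"k2p"`.
#' @param gap_mode only `"pairwise_deletion"` is implemented.
#' @return a `dist_matrix`: labelled symmetric numeric matrix.
#' @export
compute_distances <- function(aln, model = c("p", "jc69", "k2p"),
                              gap_mode = "pairwise_deletion") {
  model <- match.arg(model)
  if (!identical(gap_mode, "pairwise_deletion"))
    stop_validation("unsupported gap_mode: %s", gap_mode)
  stopifnot(inherits(aln, "dna_alignment"))
  m <- aln$seq
  m[m == "U"] <- "T"
  usable <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- length(aln$taxa)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  purine <- matrix(m %in% c("A", "G"), nrow = nrow(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mask <- usable[i, ] & usable[j, ]
      nc <- sum(mask)
      if (nc == 0)
        stop_validation("incomparable pair (%s, %s): no ungapped unambiguous site in common",
                        aln$taxa[i], aln$taxa[j])
      diff <- m[i, mask] != m[j, mask]
      p <- mean(diff)
      d <- switch(model,
        p = p,
        jc69 = {
          if (p >= 0.75)
            stop_computation("JC69 distance saturated for pair (%s, %s): p = %.4f >= 0.75",
                             aln$taxa[i], aln$taxa[j], p)
          -0.75 * log(1 - 4 * p / 3)
        },
        k2p = {
          ts <- diff & (purine[i, mask] == purine[j, mask])
          P <- mean(ts)
          Q <- p - P
          w1 <- 1 - 2 * P - Q
          w2 <- 1 - 2 * Q
          if (w1 <= 0 || w2 <= 0)
            stop_computation("K2P distance undefined for pair (%s, %s): log argument <= 0",
                             aln$taxa[i], aln$taxa[j])
          -0.5 * log(w1) - 0.25 * log(w2)
        })
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  structure(D, class = c("dist_matrix", class(D)))
}

# Validate and normalise a distance-matrix argument.
as_distance_input <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  D <- unclass(dm)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_validation("distance input must be a square matrix or dist object")
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (max(abs(D - t(D))) > 1e-8)
    stop_validation("distance matrix is not symmetric")
  if (any(D < 0))
    stop_validation("distance matrix has negative entries")
  if (any(abs(diag(D)) > 1e-12))
    stop_validation("distance matrix diagonal is not zero")
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` with `R_i = sum_k d(i,k)`. Ties are
#' broken deterministically by the smallest `(row, column)` index pair.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sister branch (the pair's summed length is preserved). The result is
#' unrooted (basal trichotomy).
#'
#' @param dm a `dist_matrix`, plain labelled matrix, or `dist` object
#'   (symmetric, nonnegative, zero diagonal), >= 3 labels.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  D <- as_distance_input(dm)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop_validation("neighbor joining needs >= 3 taxa, got %d", n)

  fmt <- function(x) sprintf("%.12g", x)
  frag <- paste0("x", seq_len(n)) # placeholder tip labels, remapped at the end
  active <- frag

  while (length(active) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", active[i], fmt(bi), active[j], fmt(bj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "merged")
    D <- D2
    active <- c(active[keep], merged)
  }

  # three-point formulas close the star
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  a <- max(0, (d12 + d13 - d23) / 2)
  b <- max(0, (d12 + d23 - d13) / 2)
  cc <- max(0, (d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 active[1], fmt(a), active[2], fmt(b), active[3], fmt(cc))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^x", "", tree$tip.label))]
  tree
}

# Map each internal non-root node to its canonical bipartition id: the tip
# set on its side of the parent edge, complemented if it contains the
# lexicographically smallest taxon, sorted, and joined with "|".
node_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[ch]])
  }
  root <- nt + 1L
  internal <- setdiff(seq_len(nt + tree$Nnode)[-seq_len(nt)], root)
  ids <- character(0)
  for (v in internal) {
    set <- desc[[v]]
    if (length(set) < 2 || length(set) > nt - 2) {
      ids[as.character(v)] <- NA_character_
      next
    }
    if (ref %in% set) set <- setdiff(tree$tip.label, set)
    ids[as.character(v)] <- paste(sort(set), collapse = "|")
  }
  ids
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the taxa in two; the split
#' is identified by the sorted tip set on the side not containing the
#' lexicographically first taxon.
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical split identifiers.
#' @export
bipartitions <- function(tree) {
  ids <- node_bipartitions(tree)
  sort(unique(ids[!is.na(ids)]))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the reference tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times; each replicate is
#' run through [compute_distances()] and [nj_tree()], and the support of an
#' internal edge of the reference tree is the percentage of replicate trees
#' containing the same bipartition. Replicates in which a pair becomes
#' incomparable (or a distance correction is undefined) are skipped and
#' counted; a warning is raised when more than 10% are skipped. Each
#' replicate draws from its own deterministic substream of `seed`, so
#' identical seeds give identical supports.
#'
#' @param aln a [dna_alignment()].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @inheritParams compute_distances
#' @return the reference `phylo` tree with supports (percent, 0-100) as
#'   internal node labels (the root label is empty), and a `bootstrap`
#'   attribute recording replicates used and skipped.
#' @export
bootstrap_support <- function(aln, replicates = 100, seed = 1,
                              model = c("p", "jc69", "k2p"),
                              gap_mode = "pairwise_deletion") {
  model <- match.arg(model)
  stopifnot(inherits(aln, "dna_alignment"))
  if (replicates < 1) stop_validation("replicates must be >= 1")
  ref <- nj_tree(compute_distances(aln, model, gap_mode))
  ref_splits <- node_bipartitions(ref)
  tally <- stats::setNames(numeric(length(ref_splits)), names(ref_splits))
  ok <- 0L; skipped <- 0L
  L <- aln$length
  for (r in seq_len(replicates)) {
    set.seed(substream_seed(seed, paste0("bootstrap:", r)))
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- structure(list(taxa = aln$taxa,
                              seq = aln$seq[, cols, drop = FALSE],
                              length = L),
                         class = "dna_alignment")
    rep_tree <- tryCatch(
      nj_tree(compute_distances(rep_aln, model, gap_mode)),
      endodiv_validation_error = function(e) NULL,
      endodiv_computation_error = function(e) NULL)
    if (is.null(rep_tree)) { skipped <- skipped + 1L; next }
    ok <- ok + 1L
    present <- bipartitions(rep_tree)
    hit <- !is.na(ref_splits) & ref_splits %in% present
    tally[hit] <- tally[hit] + 1
  }
  if (skipped > 0.1 * replicates)
    warning(sprintf("%d of %d bootstrap replicates skipped (incomparable pairs or undefined distances)",
                    skipped, replicates))
  nt <- length(ref$tip.label)
  node.label <- rep("", ref$Nnode)
  for (v in names(ref_splits)) {
    if (is.na(ref_splits[[v]])) next
    supp <- if (ok > 0) 100 * tally[[v]] / ok else NA_real_
    node.label[as.integer(v) - nt] <- sprintf("%.6g", supp)
  }
  ref$node.label <- node.label
  attr(ref, "bootstrap") <- list(replicates = replicates, used = ok,
                                 skipped = skipped, seed = seed,
                                 model = model)
  ref
}

quote_newick_label <- function(x) {
  needs <- grepl("[][ \t():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Serialise a tree to Newick
#'
#' Writes `label:length` branches, internal node labels (e.g. bootstrap
#' supports) and a trailing semicolon. Labels containing Newick
#' metacharacters (whitespace, parentheses, brackets, colon, semicolon,
#' comma, quote) are single-quoted.
#'
#' @param tree a `phylo` object.
#' @param path output path; `NULL` returns the string instead.
#' @param digits significant digits for branch lengths.
#' @return the path (or the Newick string when `path` is `NULL`), invisibly.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  root <- nt + 1L
  n_nodes <- nt + tree$Nnode
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n_nodes)))
  edge_len <- rep(NA_real_, n_nodes)
  if (!is.null(tree$edge.length)) edge_len[tree$edge[, 2]] <- tree$edge.length
  tip_labs <- quote_newick_label(tree$tip.label)
  node_labs <- tree$node.label %||% rep("", tree$Nnode)
  node_labs <- ifelse(nzchar(node_labs), quote_newick_label(node_labs), "")
  fmt_len <- function(v) {
    if (is.na(v)) "" else paste0(":", sprintf("%.*g", digits, v))
  }
  rec <- function(v) {
    if (v <= nt) return(paste0(tip_labs[v], fmt_len(edge_len[v])))
    inner <- paste(vapply(children[[v]], rec, character(1)), collapse = ",")
    lab <- node_labs[v - nt]
    if (v == root) paste0("(", inner, ")", lab)
    else paste0("(", inner, ")", lab, fmt_len(edge_len[v]))
  }
  nwk <- paste0(rec(root), ";")
  if (is.null(path)) return(invisible(nwk))
  writeLines(nwk, path)
  invisible(path)
}

#' Parse a Newick file (or string)
#'
#' @param path file path, or a literal Newick string via `text`.
#' @param text optional Newick string.
#' @return a `phylo` object with quoting undone on labels.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop_validation("could not parse Newick input")
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- unquote_newick_label(tree$node.label)
  tree
}
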