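make_fasta <- function(seqs, labels = names(seqs)) {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", labels), seqs)), tmp)
  tmp
}

test_that("FASTA reading validates shape and truncates labels at whitespace", {
  f <- make_fasta(c("ACGT", "ACGA", "AC-T"), c("PT09 extra words", "B", "C"))
  aln <- read_fasta(f)
  expect_equal(aln$taxa, c("PT09", "B", "C"))
  expect_equal(aln$length, 4)

  expect_error(read_fasta(make_fasta(c("ACGT", "ACGA"), c("A", "B"))),
               "insufficient", class = "endodiv_validation_error")
  expect_error(read_fasta(make_fasta(c("ACGT", "ACG", "ACGT"),
                                     c("A", "Bshort", "C"))),
               "Bshort", class = "endodiv_validation_error")
  expect_error(read_fasta(make_fasta(c("ACGT", "ACGA", "ACGT"),
                                     c("A", "A", "C"))),
               class = "endodiv_validation_error")
})

test_that("pairwise distances follow the stated models under pairwise deletion", {
  aln <- dna_alignment(c(A = "ACGT", B = "ACGA", C = "AC-T"))
  Dp <- compute_distances(aln, "p")
  expect_equal(Dp["A", "B"], 0.25)
  expect_equal(Dp["A", "C"], 0)   # 3 comparable sites, all equal
  expect_equal(Dp, t(Dp))

  # JC69 at p = 0.25: -(3/4) ln(1 - 1/3), evaluated independently
  aln2 <- dna_alignment(c(A = "ACGT", B = "ACGA", C = "ACGT"))
  Dj <- compute_distances(aln2, "jc69")
  expect_equal(Dj["A", "B"], 0.3040988, tolerance = 1e-6)

  # saturation and incomparability raise typed errors
  sat <- dna_alignment(c(A = "AAAA", B = "CCCC", C = "AAAA"))
  expect_error(compute_distances(sat, "jc69"), "saturated",
               class = "endodiv_computation_error")
  gappy <- dna_alignment(c(A = "AA--", B = "--AA", C = "AAAA"))
  expect_error(compute_distances(gappy, "p"), "incomparable",
               class = "endodiv_validation_error")
})

test_that("distances agree with ape::dist.dna on simulated data", {
  tree <- read_newick(text = "((a:0.15,b:0.1):0.05,(c:0.2,d:0.1):0.08,e:0.3);")
  aln <- evolve_sequences(tree, 800, seed = 5)
  bin <- ape::as.DNAbin(aln$seq)
  for (pair in list(c("p", "raw"), c("jc69", "JC69"), c("k2p", "K80"))) {
    mine <- unclass(compute_distances(aln, pair[1]))
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10,
                 info = pair[1])
  }
})

test_that("neighbor joining resolves the three-point and equidistant cases", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(D)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)

  D4 <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D4) <- 0
  t4a <- nj_tree(D4)
  t4b <- nj_tree(D4)
  expect_equal(sum(t4a$edge.length), 4)
  expect_identical(write_newick(t4a), write_newick(t4b)) # tie-break is fixed
  # the stated tie-break joins the first index pair (A, B)
  expect_setequal(bipartitions(t4a), paste(sort(c("C", "D")), collapse = "|"))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "endodiv_validation_error")
  Dneg <- D; Dneg[1, 2] <- Dneg[2, 1] <- -1
  expect_error(nj_tree(Dneg), class = "endodiv_validation_error")
  Dasym <- D; Dasym[1, 2] <- 3.5
  expect_error(nj_tree(Dasym), class = "endodiv_validation_error")
})

test_that("NJ recovers additive matrices exactly, matching ape::nj", {
  for (seed in 1:15) {
    n <- sample(4:12, 1)
    case <- random_additive_case(seed, n)
    mine <- nj_tree(case$D)
    expect_setequal(bipartitions(mine), bipartitions(case$tree))
    # branch lengths are recovered too (additive input)
    expect_equal(sum(mine$edge.length), sum(case$tree$edge.length),
                 tolerance = 1e-9)
    expect_setequal(bipartitions(mine), bipartitions(ape::nj(case$D)))
  }
})

test_that("bootstrap supports are deterministic and track signal", {
  # every column carries the same split: resampling cannot erase it
  aln <- dna_alignment(c(A = strrep("A", 60), B = strrep("A", 60),
                         C = strrep("T", 60), D = strrep("T", 60)))
  bs <- bootstrap_support(aln, replicates = 100, seed = 3)
  supports <- as.numeric(bs$node.label[nzchar(bs$node.label)])
  expect_equal(supports, 100)

  bs2 <- bootstrap_support(aln, replicates = 100, seed = 3)
  expect_identical(bs$node.label, bs2$node.label)
  bs3 <- bootstrap_support(aln, replicates = 100, seed = 4)
  expect_s3_class(bs3, "phylo") # different seed still valid

  # paired simulation: signal beats i.i.d. noise in median internal support
  tree <- read_newick(text = "(((a:0.2,b:0.2):0.1,c:0.3):0.08,(d:0.2,e:0.25):0.1,f:0.4);")
  signal <- evolve_sequences(tree, 500, seed = 11)
  set.seed(substream_seed(11, "noise"))
  noise <- dna_alignment(matrix(sample(c("A", "C", "G", "T"), 6 * 500,
                                       replace = TRUE),
                                nrow = 6,
                                dimnames = list(letters[1:6], NULL)))
  bs_sig <- bootstrap_support(signal, replicates = 50, seed = 7)
  bs_noise <- bootstrap_support(noise, replicates = 50, seed = 7)
  med <- function(t) median(as.numeric(t$node.label[nzchar(t$node.label)]))
  expect_gt(med(bs_sig), med(bs_noise))
  rng <- as.numeric(bs_noise$node.label[nzchar(bs_noise$node.label)])
  expect_true(all(rng >= 0 & rng <= 100))
})

test_that("Newick output round-trips topology, lengths and supports", {
  case <- random_additive_case(42, 10)
  tree <- nj_tree(case$D)
  tree$node.label <- c("", sprintf("%.6g", seq(10, 80, length.out = tree$Nnode - 1)))
  tmp <- tempfile(fileext = ".nwk")
  write_newick(tree, tmp)
  back <- read_newick(tmp)
  expect_setequal(bipartitions(back), bipartitions(tree))
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tree$node.label)

  # metacharacter labels get quoted and survive the round trip
  star <- nj_tree(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                         dimnames = list(c("sp one", "B", "C"),
                                         c("sp one", "B", "C"))))
  s <- write_newick(star)
  expect_match(s, "'sp one'", fixed = TRUE)
  expect_setequal(read_newick(text = s)$tip.label, c("sp one", "B", "C"))
})
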