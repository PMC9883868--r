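# Independent brute-force oracles and generators used across the suite.
# These transcribe the displayed formulas as literal loops so they stay
# independent of the package's vectorised implementations.

oracle_indices <- function(counts) {
  Nt <- 0
  for (n in counts) Nt <- Nt + n
  S <- length(counts)
  H <- 0; lam <- 0; PIE <- 0
  for (n in counts) {
    Pi <- n / Nt
    H <- H - Pi * log(Pi)
    lam <- lam + Pi^2
    if (Nt > 1) PIE <- PIE + (n / Nt) * (Nt - n) / (Nt - 1)
  }
  list(S = S,
       D_margalef = if (Nt > 1) (S - 1) / log(Nt) else NaN,
       H_shannon = H,
       D_simpson = 1 - lam,
       lambda_dominance = lam,
       PIE = if (Nt > 1) PIE else NaN,
       J_pielou = if (S > 1) H / log(S) else NaN)
}

oracle_anova_F <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (y in g) ssw <- ssw + (y - mean(g))^2
  }
  k <- length(groups); N <- length(all_y)
  (ssb / (k - 1)) / (ssw / (N - k))
}

oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

random_abundance <- function(seed, max_S = 20, max_Nt = 200) {
  set.seed(seed)
  S <- sample(2:max_S, 1)
  # positive counts summing to at most max_Nt
  counts <- 1 + stats::rmultinom(1, sample(0:(max_Nt - S), 1),
                                 rep(1 / S, S))[, 1]
  names(counts) <- paste0("G", seq_len(S))
  counts
}

# random unrooted binary tree with branch lengths in [0.1, 1] and its exact
# path-length distance matrix
random_additive_case <- function(seed, n) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = stats::cophenetic(tr))
}

empirical_tuber_counts <- function() {
  c(Aspergillus = 6, Fusarium = 6, Lecanicillium = 3, Talaromyces = 3,
    Bjerkandera = 2, Cladosporium = 2, Clonostachys = 1, Meyerozyma = 1,
    Penicillium = 1, Pseudoechria = 1, Trichoderma = 1, Zygosporium = 1)
}
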