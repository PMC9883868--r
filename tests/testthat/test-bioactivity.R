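test_that("inhibition rate follows the control-relative formula", {
  full <- inhibition_rate(radicle_assay("x", c(0, 0, 0), c(20, 21, 19)))
  expect_equal(full$rate_pct, 100)
  expect_equal(full$band, "complete")

  none <- inhibition_rate(radicle_assay("x", c(20, 20, 20), c(20, 20, 20)))
  expect_true(none$ni)
  expect_equal(none$band, "NI")

  r <- inhibition_rate(radicle_assay("x", c(5, 5, 5), c(20, 20, 20)))
  expect_equal(r$rate_pct, 75)
  expect_equal(r$sd_pct, 0)
  expect_equal(r$band, "potent")

  expect_error(inhibition_rate(radicle_assay("x", c(1, 2), c(0, 0))),
               class = "endodiv_computation_error")
})

test_that("inhibition rate is scale invariant", {
  set.seed(10)
  for (i in 1:20) {
    treated <- runif(3, 2, 12)
    control <- runif(3, 10, 25)
    k <- runif(1, 0.1, 50)
    r1 <- inhibition_rate(radicle_assay("x", treated, control))
    r2 <- inhibition_rate(radicle_assay("x", k * treated, k * control))
    expect_equal(r1$rate_pct, r2$rate_pct, tolerance = 1e-10)
    expect_equal(r1$sd_pct, r2$sd_pct, tolerance = 1e-10)
  }
})

test_that("the packaged screen reproduces the published filter counts", {
  screen <- pinellia_phytotoxicity()
  expect_equal(nrow(screen), 77)
  bands <- classify_bands(screen)
  expect_equal(bands[["complete"]], 22)
  expect_equal(bands[["strong"]], 16)
  expect_equal(bands[["potent"]], 9)
  expect_equal(bands[["weak"]], 25)
  expect_equal(bands[["NI"]], 5)
  expect_equal(sum(bands), 77)
  expect_equal(count_over(screen, 50, strict = TRUE), 52)

  # every complete/strong strain, and the over-60 potent ones, are in the
  # over-50 set; bands partition the non-NI strains
  over50 <- screen$strain_code[!screen$ni & screen$rate_pct > 50]
  high <- screen$strain_code[!screen$ni & screen$rate_pct >= 60]
  expect_true(all(high %in% over50))
  expect_equal(sum(bands[c("complete", "strong", "potent", "weak")]),
               77 - sum(screen$ni))
})

test_that("band classification handles edges and empty input", {
  empty <- classify_bands(data.frame(rate_pct = numeric(0), ni = logical(0)))
  expect_true(all(empty == 0))
  edges <- data.frame(rate_pct = c(100, 99.9, 80, 79.9, 60, 59.9, 10, 9.9, NA),
                      ni = c(rep(FALSE, 8), TRUE))
  got <- band_of(edges$rate_pct, edges$ni)
  expect_equal(got, c("complete", "strong", "strong", "potent", "potent",
                      "weak", "weak", "NI", "NI"))
})

test_that("one-way ANOVA with LSD matches its contracts", {
  same <- one_way_anova_lsd(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_false(any(same$pairwise$significant))

  # two groups: F is the square of the pooled t statistic
  a <- c(1.2, 3.4, 2.2, 4.1); b <- c(2.0, 5.5, 4.4)
  res <- one_way_anova_lsd(list(a, b))
  expect_equal(res$F, oracle_t_pooled(a, b)^2, tolerance = 1e-10)

  sig <- one_way_anova_lsd(list(c(0, 0, 1), c(10, 10, 11)), alpha = 0.05)
  expect_equal(sig$F, oracle_anova_F(list(c(0, 0, 1), c(10, 10, 11))),
               tolerance = 1e-10)
  expect_true(sig$pairwise$significant[1])

  expect_error(one_way_anova_lsd(list(c(1, 1), c(1, 1))),
               class = "endodiv_computation_error")
  expect_error(one_way_anova_lsd(list(c(1), c(1, 2))),
               class = "endodiv_validation_error")
})

test_that("ANOVA F matches the brute-force decomposition on random inputs", {
  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(2:6, 1), mean = runif(1, 0, 5), sd = runif(1, 0.5, 2)))
    res <- one_way_anova_lsd(groups)
    expect_equal(res$F, oracle_anova_F(groups), tolerance = 1e-9)
  }
})

test_that("two-sample t test covers both variants and degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(t_test(x, x), list(t = 0, p = 1, df = 4))
  shifted <- t_test(x, x + 10)
  expect_lt(shifted$p, 0.05)
  expect_equal(shifted$t, oracle_t_pooled(x, x + 10), tolerance = 1e-10)

  # equal variances and n: Welch reduces to pooled
  set.seed(5)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(t_test(a, b, "pooled")$t, t_test(a, b, "welch")$t,
               tolerance = 1e-10)

  expect_equal(t_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
})

test_that("the compound screen summary matches the published profile", {
  zones <- pinellia_antibacterial()
  s <- screen_summary(zones)
  per <- s$per_sample
  expect_true(per$active_all[per$sample_id == "compound_5"])
  expect_equal(per$n_active[per$sample_id == "compound_1"], 0)
  expect_equal(per$n_active[per$sample_id == "compound_6"], 0)
  expect_equal(s$n_organisms, 4)
  # strongest zone against P. syringae is compound 5 (40.2 mm)
  ps <- s$ranking[["P_syringae"]]
  expect_equal(ps$sample_id[1], "compound_5")
  expect_equal(ps$izd_mm[1], 40.2)
})

test_that("screen summary counts >=1 and all-organism activity correctly", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\torganism\tmic_ug_ml\tizd_mm\tizd_sd_mm",
               "s1\torgA\t>100\tNI\tNA",
               "s1\torgB\t>100\tNI\tNA",
               "s2\torgA\t25\t12.0\t0.5",
               "s2\torgB\t>100\tNI\tNA"), tmp)
  s <- screen_summary(read_zone_table(tmp))
  expect_equal(s$n_active_any, 1)
  expect_equal(s$n_active_all, 0)

  writeLines(c("sample_id\torganism\tmic_ug_ml\tizd_mm\tizd_sd_mm",
               "s1\torgA\t>100\tNI\tNA"), tmp)
  expect_equal(screen_summary(read_zone_table(tmp))$n_active_any, 0)
})

test_that("zone table validation enforces disc diameter and the MIC ladder", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\torganism\tmic_ug_ml\tizd_mm\tizd_sd_mm",
               "s1\torgA\t25\t4.0\t0.5"), tmp)
  expect_error(read_zone_table(tmp), "6 mm",
               class = "endodiv_validation_error")
  writeLines(c("sample_id\torganism\tmic_ug_ml\tizd_mm\tizd_sd_mm",
               "s1\torgA\t37\t12.0\t0.5"), tmp)
  expect_error(read_zone_table(tmp), "ladder",
               class = "endodiv_validation_error")
})
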