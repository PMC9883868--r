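# Bioassay arithmetic: radicle-growth inhibition rates with activity
# banding, filter counts over the phytotoxicity screen, ANOVA/LSD and t
# statistics, and disc-diffusion (IZD/MIC) screen summaries.

BAND_LEVELS <- c("complete", "strong", "potent", "weak", "NI")

# twofold dilution ladder as printed (3.13 ~ 3.125, 1.56 ~ 1.5625)
MIC_LADDER <- c(100, 50, 25, 12.5, 6.25, 3.13, 1.56)

#' Construct a radicle-elongation assay record
#'
#' @param sample_id strain or compound identifier.
#' @param treated replicate radicle lengths (mm) under treatment.
#' @param control replicate radicle lengths (mm) under the water control.
#' @return a `radicle_assay` list.
#' @export
radicle_assay <- function(sample_id, treated, control) {
  if (length(treated) == 0 || length(control) == 0)
    stop_validation("treated and control replicate lists must be non-empty")
  if (any(treated < 0) || any(control < 0))
    stop_validation("radicle lengths must be nonnegative")
  structure(list(sample_id = as.character(sample_id),
                 treated = as.numeric(treated),
                 control = as.numeric(control)),
            class = "radicle_assay")
}

band_of <- function(rate_pct, ni = FALSE) {
  ifelse(ni | is.na(rate_pct), "NI",
  ifelse(abs(rate_pct - 100) < 1e-9, "complete",
  ifelse(rate_pct >= 80, "strong",
  ifelse(rate_pct >= 60, "potent",
  ifelse(rate_pct >= 10, "weak", "NI")))))
}

#' Inhibition rate from a radicle assay
#'
#' `rate = (mean(control) - mean(treated)) / mean(control) * 100`, clipped
#' below at zero; a nonpositive rate is reported as NI (not inhibited). The
#' standard deviation is propagated replicate-wise: each treated replicate is
#' scored against the control mean and the sd of those per-replicate rates is
#' reported.
#'
#' @param assay a [radicle_assay()].
#' @return an `inhibition_result` one-row data frame: `sample_id`,
#'   `rate_pct`, `sd_pct`, `ni`, `band`.
#' @export
inhibition_rate <- function(assay) {
  stopifnot(inherits(assay, "radicle_assay"))
  cm <- mean(assay$control)
  if (cm <= 0) stop_computation("undefined control: control mean must be > 0")
  per_rep <- (cm - assay$treated) / cm * 100
  rate <- mean(per_rep)
  sdp <- if (length(per_rep) > 1) stats::sd(per_rep) else 0
  ni <- rate <= 0
  rate <- max(0, rate)
  structure(data.frame(sample_id = assay$sample_id,
                       rate_pct = if (ni) NA_real_ else rate,
                       sd_pct = sdp, ni = ni,
                       band = band_of(rate, ni),
                       stringsAsFactors = FALSE),
            class = c("inhibition_result", "data.frame"))
}

#' Read a phytotoxicity screen table
#'
#' TSV with columns `strain_code`, `rate_pct` (percent, `"NI"` sentinel for
#' not inhibited) and `sd_pct`. The packaged survey screen is at
#' `system.file("extdata", "pinellia_phytotoxicity.tsv", package = "endodiv")`.
#'
#' @param path file path.
#' @return an `inhibition_table` data frame: `strain_code`, `rate_pct`
#'   (`NA` for NI), `sd_pct`, `ni`, `band`.
#' @export
read_phytotoxicity <- function(path) {
  if (!file.exists(path)) stop_validation("phytotoxicity file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  for (col in c("strain_code", "rate_pct", "sd_pct")) {
    if (is.null(raw[[col]]))
      stop_validation("phytotoxicity table is missing required column: %s", col)
  }
  if (anyDuplicated(raw$strain_code))
    stop_validation("duplicate strain_code in phytotoxicity table")
  ni <- raw$rate_pct == "NI"
  rate <- suppressWarnings(as.numeric(raw$rate_pct))
  if (any(is.na(rate) & !ni))
    stop_validation("non-numeric inhibition rate for: %s",
                    paste(raw$strain_code[is.na(rate) & !ni], collapse = ", "))
  rate[ni] <- NA_real_
  structure(data.frame(strain_code = raw$strain_code, rate_pct = rate,
                       sd_pct = suppressWarnings(as.numeric(raw$sd_pct)),
                       ni = ni, band = band_of(rate, ni),
                       stringsAsFactors = FALSE),
            class = c("inhibition_table", "data.frame"))
}

#' The packaged Pinellia phytotoxicity screen
#'
#' @return the transcribed 77-strain radicle-inhibition screen as an
#'   `inhibition_table`.
#' @export
pinellia_phytotoxicity <- function() {
  read_phytotoxicity(system.file("extdata", "pinellia_phytotoxicity.tsv",
                                 package = "endodiv", mustWork = TRUE))
}

#' Activity-band counts over inhibition results
#'
#' Bands are half-open on the rate scale: `complete` is exactly 100%,
#' `strong` is \[80, 100), `potent` is \[60, 80), `weak` is \[10, 60), and
#' everything below 10% (or flagged NI) is NI. Note the conventional
#' "weak 10-60%" band overlaps threshold queries such as "> 50%": use
#' [count_over()] for the latter.
#'
#' @param results an `inhibition_table` (or any data frame with `rate_pct`
#'   and `ni` columns).
#' @return named integer vector of counts per band.
#' @export
classify_bands <- function(results) {
  if (nrow(results) == 0)
    return(stats::setNames(integer(length(BAND_LEVELS)), BAND_LEVELS))
  bands <- factor(band_of(results$rate_pct, results$ni), levels = BAND_LEVELS)
  stats::setNames(as.integer(table(bands)), BAND_LEVELS)
}

#' Count results above an inhibition-rate threshold
#'
#' @param results as in [classify_bands()].
#' @param threshold percent threshold (default 50).
#' @param strict `TRUE` for `> threshold` (default), `FALSE` for `>=`.
#' @return integer count; NI entries never count.
#' @export
count_over <- function(results, threshold = 50, strict = TRUE) {
  r <- results$rate_pct
  ok <- !results$ni & !is.na(r)
  sum(ok & if (strict) r > threshold else r >= threshold)
}

#' One-way ANOVA with Fisher's LSD post hoc
#'
#' Classical between/within decomposition, followed by unprotected pairwise
#' least-significant-difference comparisons: for groups i, j the statistic is
#' `t = (mi - mj) / sqrt(MSE * (1/ni + 1/nj))` on the within-group degrees of
#' freedom, two-sided at level `alpha`.
#'
#' @param groups list of >= 2 numeric replicate vectors (each n >= 2).
#' @param alpha significance level for the pairwise flags (default 0.05).
#' @return list with `F`, `p`, `df_between`, `df_within`, `ms_within`, and
#'   `pairwise` (data frame: `group_i`, `group_j`, `diff`, `t`, `p`,
#'   `significant`).
#' @export
one_way_anova_lsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop_validation("'groups' must be a list of >= 2 replicate vectors")
  n <- lengths(groups)
  if (any(n < 2)) stop_validation("each group needs n >= 2 replicates")
  k <- length(groups)
  N <- sum(n)
  if (N - k <= 0) stop_validation("no within-group degrees of freedom")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), n))
  gm <- vapply(groups, mean, numeric(1))
  ssw0 <- sum((y - gm[as.integer(g)])^2)
  ssb0 <- sum(n * (gm - mean(y))^2)
  if (ssb0 == 0 && ssw0 == 0)
    stop_computation("indeterminate F: zero between- and within-group variance")
  fit <- stats::lm(y ~ g)
  # anova.lm warns on numerically perfect fits; the degenerate case is
  # already rejected above and the remaining F values are exact
  tab <- suppressWarnings(stats::anova(fit))
  Fstat <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  mse <- tab$`Mean Sq`[2]
  dfw <- tab$Df[2]
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tt <- if (se == 0) 0 else (means[i] - means[j]) / se
    pp <- if (se == 0 && means[i] == means[j]) 1 else
      2 * stats::pt(-abs(tt), dfw)
    data.frame(group_i = i, group_j = j, diff = means[i] - means[j],
               t = tt, p = pp, significant = pp < alpha)
  }))
  list(F = Fstat, p = p, df_between = tab$Df[1], df_within = dfw,
       ms_within = mse, alpha = alpha, pairwise = pw)
}

#' Two-sample t test (pooled or Welch)
#'
#' Two-sided; `variant = "pooled"` (default) assumes equal variances. Samples
#' with zero pooled variance and equal means give `t = 0, p = 1` rather than
#' an error.
#'
#' @param a,b numeric replicate vectors (n >= 2 each).
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `p`, `df`.
#' @export
t_test <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop_validation("both samples need n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Read a disc-diffusion (IZD/MIC) screen table
#'
#' TSV columns: `sample_id`, `organism`, `mic_ug_ml` (a value on the twofold
#' dilution ladder 100...1.56 as printed, or the censored ceiling `">100"`),
#' `izd_mm` (mean inhibition-zone diameter, `"NI"` when inactive) and
#' `izd_sd_mm`. Active zones must be >= 6 mm (the disc diameter). The
#' packaged compound screen is at
#' `system.file("extdata", "pinellia_antibacterial.tsv", package = "endodiv")`.
#'
#' @param path file path.
#' @return a `zone_table` data frame: `sample_id`, `organism`, `mic`
#'   (numeric, ceiling value for censored), `mic_censored`, `izd_mm` (`NA`
#'   when NI), `izd_sd_mm`, `active`.
#' @export
read_zone_table <- function(path) {
  if (!file.exists(path)) stop_validation("zone table not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  for (col in c("sample_id", "organism", "mic_ug_ml", "izd_mm", "izd_sd_mm"))
    if (is.null(raw[[col]]))
      stop_validation("zone table is missing required column: %s", col)
  ni <- raw$izd_mm == "NI"
  izd <- suppressWarnings(as.numeric(raw$izd_mm))
  if (any(is.na(izd) & !ni))
    stop_validation("non-numeric IZD entries present (expected mm or 'NI')")
  izd[ni] <- NA_real_
  if (any(!is.na(izd) & izd < 6))
    stop_validation("active IZD below the 6 mm disc diameter")
  censored <- grepl("^>", raw$mic_ug_ml)
  mic <- suppressWarnings(as.numeric(sub("^>", "", raw$mic_ug_ml)))
  if (any(is.na(mic)))
    stop_validation("non-numeric MIC entries present")
  off_ladder <- !censored & !vapply(mic, function(v)
    any(abs(v - MIC_LADDER) < 1e-9), logical(1))
  if (any(off_ladder))
    stop_validation("MIC value off the twofold dilution ladder: %s",
                    paste(unique(mic[off_ladder]), collapse = ", "))
  structure(data.frame(sample_id = raw$sample_id, organism = raw$organism,
                       mic = mic, mic_censored = censored,
                       izd_mm = izd,
                       izd_sd_mm = suppressWarnings(as.numeric(raw$izd_sd_mm)),
                       active = !ni, stringsAsFactors = FALSE),
            class = c("zone_table", "data.frame"))
}

#' The packaged Pinellia compound antibacterial screen
#'
#' @return the transcribed compound IZD/MIC screen as a `zone_table`.
#' @export
pinellia_antibacterial <- function() {
  read_zone_table(system.file("extdata", "pinellia_antibacterial.tsv",
                              package = "endodiv", mustWork = TRUE))
}

#' Summarise a disc-diffusion screen
#'
#' @param zones a `zone_table` (see [read_zone_table()]).
#' @return list: `per_sample` (data frame: `sample_id`, `n_active`,
#'   `active_any`, `active_all`), `n_active_any`, `n_active_all`,
#'   `n_organisms`, and `ranking` (per-organism data frames of active
#'   samples ordered by IZD descending; censored MICs sort after measured
#'   ones at equal IZD).
#' @export
screen_summary <- function(zones) {
  stopifnot(inherits(zones, "zone_table"))
  organisms <- unique(zones$organism)
  samples <- unique(zones$sample_id)
  n_active <- vapply(samples, function(s)
    sum(zones$active[zones$sample_id == s]), integer(1))
  per_sample <- data.frame(sample_id = samples, n_active = n_active,
                           active_any = n_active >= 1,
                           active_all = n_active == length(organisms),
                           stringsAsFactors = FALSE, row.names = NULL)
  ranking <- lapply(organisms, function(org) {
    sub <- zones[zones$organism == org & zones$active, , drop = FALSE]
    sub[order(-sub$izd_mm, sub$mic_censored, sub$mic), , drop = FALSE]
  })
  names(ranking) <- organisms
  list(per_sample = per_sample,
       n_active_any = sum(per_sample$active_any),
       n_active_all = sum(per_sample$active_all),
       n_organisms = length(organisms),
       ranking = ranking)
}
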