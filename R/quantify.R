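# Scalar quantification calculators: morphometry ratios, pooled percentages,
# delta-delta-Ct relative expression, protein/DNA ratio, and densitometry
# normalization. Percentages are reported both unrounded and rounded to the
# nearest percent (prose conventionally uses the rounded value).

#' Relative cell count from thickness x cells-per-field morphometry
#'
#' `100 * (cells_test * thickness_test) / (cells_ref * thickness_ref)`.
#'
#' @param test,reference Lists (or one-row data.frames) with `cells` (cells
#'   per field of view) and `thickness_um`; all values must be positive.
#' @return List: `percent` (unrounded), `percent_rounded`.
#' @export
relative_cell_count <- function(test, reference) {
  for (r in list(test, reference)) {
    if (r$cells <= 0 || r$thickness_um <= 0) {
      stopf("cells and thickness must be positive")
    }
  }
  p <- 100 * (test$cells * test$thickness_um) /
    (reference$cells * reference$thickness_um)
  list(percent = p, percent_rounded = round(p))
}

#' Percent difference (how much lower the test mean is than the reference)
#'
#' `100 * (1 - test / ref)`.
#'
#' @param test_mean,ref_mean Group means; `ref_mean > 0`.
#' @return List: `percent` (unrounded), `percent_rounded`.
#' @export
percent_difference <- function(test_mean, ref_mean) {
  check_number(ref_mean, "ref_mean", 0, strict = TRUE)
  p <- 100 * (1 - test_mean / ref_mean)
  list(percent = p, percent_rounded = round(p))
}

#' Pooled percentage across groups
#'
#' `100 * sum(successes) / sum(totals)` — e.g. pooling non-arrhythmic
#' burst-pacing attempts across experimental groups.
#'
#' @param successes,totals Integer vectors of equal length.
#' @return List: `percent` (unrounded), `percent_rounded`.
#' @export
pooled_percent <- function(successes, totals) {
  if (length(successes) != length(totals)) stopf("length mismatch")
  if (any(totals <= 0) || any(successes < 0) || any(successes > totals)) {
    stopf("need 0 <= successes <= totals with positive totals")
  }
  p <- 100 * sum(successes) / sum(totals)
  list(percent = p, percent_rounded = round(p))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged (arithmetic mean on the log-scale Ct
#' values) per sample and gene; then
#' `dCt = Ct_target - Ct_housekeeping` per sample,
#' `ddCt = dCt_sample - dCt_reference`, expression `= 2^(-ddCt)`.
#' The reference sample maps to 1.0 by construction.
#'
#' @param table Long-format data.frame with columns `sample`, `gene`, `ct`
#'   (one row per replicate; Ct values must be finite).
#' @param target Target gene name.
#' @param sample Sample whose expression is wanted.
#' @param reference_sample Calibrator sample.
#' @param housekeeping Housekeeping gene (default `"GAPDH"`); must be
#'   present for every sample involved.
#' @return List: `expression`, `dct_sample`, `dct_reference`, `ddct`.
#' @export
ddct <- function(table, target, sample, reference_sample,
                 housekeeping = "GAPDH") {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(table))) {
    stopf("Ct table needs columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(table$ct))) stopf("Ct values must be finite")
  mean_ct <- function(s, g) {
    v <- table$ct[table$sample == s & table$gene == g]
    if (!length(v)) stopf("no Ct rows for sample '%s', gene '%s'", s, g)
    mean(v)
  }
  dct_s <- mean_ct(sample, target) - mean_ct(sample, housekeeping)
  dct_r <- mean_ct(reference_sample, target) -
    mean_ct(reference_sample, housekeeping)
  dd <- dct_s - dct_r
  list(expression = 2^(-dd), dct_sample = dct_s, dct_reference = dct_r,
       ddct = dd)
}

#' Protein/DNA ratio
#'
#' @param protein_ug,dna_ug Masses in ug; `dna_ug > 0`.
#' @return `protein_ug / dna_ug`.
#' @export
protein_dna_ratio <- function(protein_ug, dna_ug) {
  check_number(dna_ug, "dna_ug", 0, strict = TRUE)
  protein_ug / dna_ug
}

#' Densitometry normalization against a loading control
#'
#' Per lane, `level = band / control`; levels are then reported relative to
#' the reference group's mean level (so the reference group averages exactly
#' 1.0).
#'
#' @param band,control Positive band and loading-control intensities, one
#'   per lane.
#' @param group Group label per lane.
#' @param reference_group Group whose mean maps to 1.0.
#' @return data.frame with `group`, `level` (band/control) and `relative`.
#' @export
densitometry_normalize <- function(band, control, group, reference_group) {
  if (any(control <= 0)) stopf("zero or negative loading-control intensity")
  if (any(band < 0)) stopf("band intensities must be non-negative")
  if (!reference_group %in% group) {
    stopf("reference group '%s' not present", reference_group)
  }
  level <- band / control
  ref_mean <- mean(level[group == reference_group])
  data.frame(group = group, level = level, relative = level / ref_mean)
}
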