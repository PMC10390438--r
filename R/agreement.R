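# Agreement statistics: Pearson correlation with t-test p-value,
# Bland-Altman limits of agreement (mean +/- 2 SD), relative percentage
# difference, and pairwise modality comparison tables.

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation with the two-sided t-test p-value on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-degenerate
#'   variance.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman limits of agreement
#'
#' Pairwise differences `d = x - y`; returns the mean difference and the
#' limits `mean(d) +/- 2 * sd(d)` with the sample (n - 1) standard
#' deviation.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `mean_diff`, `lower`, `upper`, `sd_diff` and `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, lower = m - 2 * s, upper = m + 2 * s,
       sd_diff = s, n = length(x))
}

#' Relative percentage difference
#'
#' `100 * (estimated - theoretical) / theoretical`.
#'
#' @param estimated,theoretical Numeric; `theoretical` must be positive.
#' @return Relative difference in percent.
#' @export
relative_percent_difference <- function(estimated, theoretical) {
  if (any(theoretical <= 0)) stop("`theoretical` must be positive")
  100 * (estimated - theoretical) / theoretical
}

#' Pairwise agreement between uptake modalities
#'
#' For a per-case table of thyroid uptake by modality, computes Pearson
#' correlation and Bland-Altman agreement for each of the three pairs
#' Planar vs Tomo-AC, Planar vs Tomo-NoAC and Tomo-AC vs Tomo-NoAC.
#'
#' @param tu_table Data.frame with numeric columns `planar`, `tomo_ac`,
#'   `tomo_noac`, one row per case (>= 3 complete cases).
#' @return A data.frame with one row per pair: `pair`, `r`, `p_value`,
#'   `mean_diff`, `lower`, `upper`, `n`.
#' @export
modality_agreement <- function(tu_table) {
  need <- c("planar", "tomo_ac", "tomo_noac")
  if (!all(need %in% names(tu_table)))
    stop("`tu_table` needs columns planar, tomo_ac, tomo_noac")
  cc <- stats::complete.cases(tu_table[need])
  if (sum(cc) < 3L)
    stop(sprintf("need >= 3 complete cases; incomplete rows: %s",
                 paste(which(!cc), collapse = ", ")))
  tab <- tu_table[cc, need]
  pairs <- list(c("planar", "tomo_ac"), c("planar", "tomo_noac"),
                c("tomo_ac", "tomo_noac"))
  do.call(rbind, lapply(pairs, function(p) {
    pe <- pearson(tab[[p[1]]], tab[[p[2]]])
    ba <- bland_altman(tab[[p[1]]], tab[[p[2]]])
    data.frame(pair = paste(p, collapse = " vs "),
               r = pe$r, p_value = pe$p_value,
               mean_diff = ba$mean_diff, lower = ba$lower, upper = ba$upper,
               n = pe$n)
  }))
}
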