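# shared helpers: percentage formatting, rounding, input checks

#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; summary tables here follow the
#' half-up convention of the published report shapes (e.g. 0.247% prints
#' as 0.25%).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format a count as a percentage of a total
#'
#' Renders `100 * n / total` rounded half-up to two decimals with trailing
#' zeros (`"0.00%"`). With `legacy = TRUE`, whole-number percentages drop
#' the decimals (`"0%"`, `"100%"`), matching the mixed style some published
#' summary tables use. A zero total renders as an en dash.
#'
#' @param n count (numerator), vectorized.
#' @param total denominator, vectorized.
#' @param legacy drop decimals for whole-number percentages.
#' @param empty string rendered when `total` is 0.
#' @return character vector.
#' @export
format_percent <- function(n, total, legacy = FALSE, empty = "–") {
  stopifnot(length(n) == length(total) || length(total) == 1)
  total <- rep_len(total, length(n))
  out <- character(length(n))
  for (i in seq_along(n)) {
    if (total[i] == 0) {
      out[i] <- empty
      next
    }
    pct <- round_half_up(100 * n[i] / total[i], 2)
    if (legacy && pct == floor(pct)) {
      out[i] <- sprintf("%d%%", as.integer(pct))
    } else {
      out[i] <- sprintf("%.2f%%", pct)
    }
  }
  out
}

#' Worst-case feeding dose from an in-planta concentration
#'
#' Maximum-hazard feeding assays expose the non-target organism to a
#' deliberate multiple of the concentration the crop actually expresses.
#'
#' @param planta_conc concentration expressed in planta (e.g. ng/g).
#' @param hazard_factor exaggeration multiple (default 100).
#' @return dose in the same units as `planta_conc`.
#' @examples
#' max_hazard_dose(4.4) # 440
#' @export
max_hazard_dose <- function(planta_conc, hazard_factor = 100) {
  stopifnot(is.numeric(planta_conc), planta_conc >= 0, hazard_factor > 0)
  planta_conc * hazard_factor
}

# internal: assert a scalar string
is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)
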