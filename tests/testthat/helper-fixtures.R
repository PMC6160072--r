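# shared fixtures: tiny cohorts and hand-built panels

small_spec <- function(n_girls = 6, n_boys = 6, ...) {
  cohort_spec(n_girls = n_girls, n_boys = n_boys, ...)
}

# panel with fully specified integer scores; R1 girls {10, 14} feeds the
# hand-computed auxiliary-statistic checks
toy_panel <- function() {
  base <- tidyr::expand_grid(id = 1:4, wave = 1:3)
  base$gender <- rep(c("girl", "girl", "boy", "boy"), each = 3)
  base$month <- c(0, 4, 7)[base$wave]
  base$rumination <- c(10, 11, 12,   14, 13, 12,   8, 9, 10,   6, 7, 8)
  base$cdi <- c(5, NA, 7,   9, NA, 8,   4, NA, 6,   3, NA, 2)
  base$stressors <- c(2, NA, 3,   4, NA, 4,   1, NA, 2,   5, NA, 3)
  base[, c("id", "gender", "wave", "month", "cdi", "rumination", "stressors")]
}

# profiles with exact integer initial conditions so that a generated
# panel's wave-1 records reproduce them verbatim
integer_profiles <- function(n_per_gender = 6) {
  tibble::tibble(
    id = seq_len(2 * n_per_gender),
    gender = rep(c("girl", "boy"), each = n_per_gender),
    D0 = rep(c(4, 8, 12, 16, 20, 9), length.out = 2 * n_per_gender),
    R0 = rep(c(6, 10, 14, 18, 8, 12), length.out = 2 * n_per_gender),
    S0 = rep(c(2, 4, 6, 8, 3, 5), length.out = 2 * n_per_gender),
    inflow = rep(c(2, 4, 6, 8, 3, 5), length.out = 2 * n_per_gender) / 6
  )
}

table2_truth <- c(theta7 = 0.0699, theta8 = 0.8894, theta9 = 1.4741)
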