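band_indices <- function(freq, band) {
  which(freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12)
}

#' Per-level second-order total variation and energy
#'
#' Diagnoses which decomposition levels carry resonance-scale structure.  For
#' the aligned level-j wavelet coefficients restricted to the analysis band,
#' the first differences \eqn{D_{1,j}(f) = \tilde W_j(f+\delta f)-\tilde W_j(f)}
#' and second differences \eqn{D_{2,j}(f) = D_{1,j}(f+\delta f)-D_{1,j}(f)}
#' give the level's second-order total variation
#' \eqn{TV_{2,j} = \sum_{f=f_1}^{f_2-2\delta f} |D_{2,j}(f)|}.
#' The coefficient energy on the same band is reported alongside; both are
#' also returned normalised to sum to one across levels.  The sharp noise,
#' scattering and water-vapour content concentrates total variation in the
#' fine levels, while the near-constant baseline levels carry almost none;
#' energy alone does not separate the levels.
#'
#' @param d An aligned `thz_modwt` with a frequency axis.
#' @param band Analysis band `(f1, f2)` in THz; defaults to the
#'   decomposition's band.
#' @return A `thz_level_profile` tibble: `level`, `tv2`, `energy`,
#'   `tv2_fraction`, `energy_fraction`.
#' @export
tv2_levels <- function(d, band = NULL) {
  if (!is_aligned(d))
    stop_thz("Level diagnostics need aligned coefficients; call `modwt_align()` first.",
             "thz_alignment_error")
  if (is.null(d$frequency))
    stop_thz("Decomposition carries no frequency axis.", "thz_invalid_input")
  band <- band %||% d$band %||% range(d$frequency)
  idx <- band_indices(d$frequency, band)
  if (length(idx) < 3L)
    stop_thz("Analysis band shorter than 3 samples.", "thz_invalid_band")
  tv2 <- apply(d$W[idx, , drop = FALSE], 2, function(w) sum(abs(diff(diff(w)))))
  energy <- apply(d$W[idx, , drop = FALSE], 2, function(w) sum(w^2))
  # a structureless (all-zero) decomposition carries no information to
  # exclude levels on: report uniform fractions so every level is retained
  frac_of <- function(v) if (sum(v) > 0) v / sum(v) else rep(1 / d$J, d$J)
  new_tibble(list(level = seq_len(d$J),
                  tv2 = unname(tv2),
                  energy = unname(energy),
                  tv2_fraction = unname(frac_of(tv2)),
                  energy_fraction = unname(frac_of(energy))),
             nrow = d$J, class = "thz_level_profile", band = band)
}

#' Keep decomposition levels by their share of total variation
#'
#' Applies the level-exclusion rule: a level is kept when its fraction of the
#' total second-order total variation lies within `[lower, upper]`.  Levels
#' above the upper bound are dominated by sharp noise/scattering transitions;
#' levels below the lower bound only carry baseline.  Bounds are inclusive.
#'
#' @param profile A `thz_level_profile` from [tv2_levels()].
#' @param upper,lower Inclusive fraction bounds (defaults 25% and 0.2%).
#' @return The profile with logical `kept` and character `reason` columns and
#'   a `kept_levels` attribute.  Erroring when no level survives.
#' @examples
#' \dontrun{
#' profile |> select_levels()
#' }
#' @export
select_levels <- function(profile, upper = 0.25, lower = 0.002) {
  fr <- profile$tv2_fraction
  kept <- fr >= lower & fr <= upper
  if (!any(kept))
    stop_thz(paste0("No decomposition level survives the total-variation bounds (",
                    lower, ", ", upper,
                    "); review the analysis band or the decomposition depth."),
             "thz_no_levels")
  out <- profile
  out$kept <- kept
  out$reason <- dplyr::case_when(
    kept ~ "kept",
    fr > upper ~ sprintf("tv2 fraction > %g", upper),
    TRUE ~ sprintf("tv2 fraction < %g", lower))
  attr(out, "kept_levels") <- profile$level[kept]
  attr(out, "bounds") <- c(lower = lower, upper = upper)
  class(out) <- unique(c("thz_level_profile", class(out)))
  out
}

kept_levels <- function(profile) {
  kl <- attr(profile, "kept_levels")
  if (is.null(kl))
    stop_thz("Run `select_levels()` before asking for kept levels.", "thz_no_levels")
  kl
}
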