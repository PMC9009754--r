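#' Tidy methods for fitted objects
#'
#' `tidy()` on a Kirchhoff fit returns one row per fitted quantity;
#' `glance()` a one-row model summary.
#'
#' @param x A `thz_kirchhoff_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.thz_kirchhoff_fit <- function(x, ...) {
  tibble(term = c("sigma_um", "r2", "slope"),
         estimate = c(x$sigma_um, x$r2, x$slope),
         std.error = c(x$sigma_se, NA_real_, x$slope_se))
}

#' @rdname tidy.thz_kirchhoff_fit
#' @export
glance.thz_kirchhoff_fit <- function(x, ...) {
  tibble(sigma_um = x$sigma_um, sigma_se = x$sigma_se, r2 = x$r2,
         slope = x$slope, residual_rms = x$residual_rms, n = x$n,
         theta_deg = x$theta_deg)
}

#' @export
tidy.thz_level_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "thz_level_profile")
  out
}
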