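# Least-asymmetric (symlet) orthonormal scaling filters, unit energy,
# Percival-Walden orientation.  sym4 is LA(8).
.la_scaling <- list(
  `8` = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
          0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
          -0.012603967262037833, 0.032223100604042702),
  `10` = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  `12` = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
           -0.048311742585632998, 0.49105594192674662, 0.787641141030194,
           0.3379294217276218, -0.072637522786462516, -0.021060292512300564,
           0.044724901770665779, 0.0017677118642428036, -0.007800708325034148),
  `14` = c(0.0026818145682578781, -0.0010473848886829163, -0.01263630340325193,
           0.03051551316596357, 0.067892693501372697, -0.049552834937127255,
           0.017441255086855827, 0.5361019170917628, 0.76776431700316405,
           0.28862963175151463, -0.14004724044296152, -0.10780823770381774,
           0.0040102448715336634, 0.010268176708511255),
  `16` = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
           0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
           -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
           0.0018899503327594609),
  `18` = c(0.0014009155259146807, 0.00061978088898558676, -0.013271967781817119,
           -0.01152821020767923, 0.03022487885827568, 0.00058346274612580684,
           -0.054568958430834071, 0.238760914607303, 0.717897082764412,
           0.61733844914093583, 0.035272488035271894, -0.19155083129728512,
           -0.018233770779395985, 0.06207778930288603, 0.0088592674934004842,
           -0.010264064027633142, -0.00047315449868008311, 0.0010694900329086053),
  `20` = c(0.00077015980911449011, 9.5632670722894754e-05, -0.0086412992770224222,
           -0.0014653825813050513, 0.045927239231092203, 0.011609893903711381,
           -0.15949427888491757, -0.070880535783243853, 0.47169066693843925,
           0.7695100370211071, 0.38382676106708546, -0.035536740473817552,
           -0.0319900568824278, 0.049994972077376687, 0.0057649120335819086,
           -0.02035493981231129, -0.00080435893201654491, 0.0045931735853118284,
           5.7036083618494284e-05, -0.00045932942100465878))

# phase parameter of the LA(L) family
la_nu <- function(L) {
  if (L %in% c(8, 12, 16, 20)) return(-L / 2 + 1)
  if (L %in% c(10, 18)) return(-L / 2)
  if (L == 14) return(-L / 2 + 2)
  stop_thz(sprintf("No phase parameter for L = %d.", L), "thz_invalid_filter")
}

#' MODWT least-asymmetric wavelet and scaling filters
#'
#' Returns the MODWT-normalised LA(L) filter pair: the orthonormal symlet
#' scaling filter divided by \eqn{\sqrt 2} (so its coefficients sum to 1 and
#' have energy 1/2) and the quadrature-mirror wavelet filter derived from it,
#' together with the family's phase parameter \eqn{\nu} used by the zero-phase
#' alignment.  LA(8) is the "sym4" filter with four vanishing moments.
#'
#' @param L Filter length, one of 8, 10, 12, 14, 16, 18, 20.
#' @return A `thz_filter_pair`: list with elements `h` (wavelet filter),
#'   `g` (scaling filter), `L`, `family` and `nu`.
#' @examples
#' fp <- la_filters(8)
#' fp$nu          # -3
#' sum(fp$g)      # 1
#' @export
la_filters <- function(L = 8) {
  key <- as.character(L)
  if (!key %in% names(.la_scaling))
    stop_thz(sprintf("Unsupported filter length %s; supported: %s.",
                     format(L), paste(names(.la_scaling), collapse = ", ")),
             "thz_invalid_filter")
  L <- as.integer(L)
  g0 <- .la_scaling[[key]]
  g <- g0 / sqrt(2)
  h <- rev(g) * (-1)^(0:(L - 1))
  fp <- structure(list(h = h, g = g, L = L,
                       family = sprintf("LA(%d)", L), nu = la_nu(L)),
                  class = "thz_filter_pair")
  validate_filter_pair(fp)
  fp
}

validate_filter_pair <- function(fp, tol = 1e-10) {
  h <- fp$h; g <- fp$g; L <- fp$L
  ok <- abs(sum(h)) < tol && abs(sum(g) - 1) < tol &&
    abs(sum(h^2) - 0.5) < tol && abs(sum(g^2) - 0.5) < tol
  if (ok) {
    for (n in seq_len(L / 2 - 1)) {
      lag <- 2 * n
      if (abs(sum(h[seq_len(L - lag)] * h[(lag + 1):L])) >= tol) ok <- FALSE
      if (abs(sum(g[seq_len(L - lag)] * g[(lag + 1):L])) >= tol) ok <- FALSE
    }
  }
  if (!ok)
    stop_thz(sprintf("Filter pair %s violates the MODWT filter identities.", fp$family),
             "thz_invalid_filter")
  invisible(fp)
}

#' @export
print.thz_filter_pair <- function(x, ...) {
  cat(sprintf("<thz_filter_pair %s, L = %d, nu = %d>\n", x$family, x$L, x$nu))
  invisible(x)
}
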