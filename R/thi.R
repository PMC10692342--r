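#' Hourly temperature-humidity index
#'
#' Combines dry-bulb temperature and relative humidity into the
#' temperature-humidity index (THI) commonly used to quantify heat load in
#' cattle:
#' \deqn{THI = (1.8 T + 32) - (0.55 - 0.0055 RH)(1.8 T - 26)}
#' with \eqn{T} in degrees Celsius and \eqn{RH} in percent. At
#' \eqn{T = 130/9 \approx 14.4}°C the humidity term vanishes and THI = 58
#' regardless of RH; above that temperature higher humidity increases THI.
#'
#' @param temp_c Numeric vector, air temperature in °C (must lie in
#'   \[-50, 60\]).
#' @param rh_pct Numeric vector, relative humidity in percent (must lie in
#'   \[0, 100\]). Recycled against `temp_c`.
#' @return Numeric vector of THI values (index units).
#' @examples
#' thi_hourly(25, 50)   # 71.775
#' thi_hourly(130 / 9, 80)  # 58, humidity-independent point
#' @export
thi_hourly <- function(temp_c, rh_pct) {
  stopifnot(is.numeric(temp_c), is.numeric(rh_pct))
  n <- max(length(temp_c), length(rh_pct))
  temp_c <- rep_len(temp_c, n)
  rh_pct <- rep_len(rh_pct, n)
  bad_t <- which(!is.na(temp_c) & (temp_c < -50 | temp_c > 60))
  if (length(bad_t)) {
    stop("temperature out of range [-50, 60] degC at record(s) ",
         paste(utils::head(bad_t, 5L), collapse = ", "),
         " (value ", temp_c[bad_t[1L]], ")")
  }
  bad_rh <- which(!is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100))
  if (length(bad_rh)) {
    stop("relative humidity out of range [0, 100] % at record(s) ",
         paste(utils::head(bad_rh, 5L), collapse = ", "),
         " (value ", rh_pct[bad_rh[1L]], ")")
  }
  (1.8 * temp_c + 32) - (0.55 - 0.0055 * rh_pct) * (1.8 * temp_c - 26)
}

#' Scaling anchors for heat-load covariates
#'
#' The weekly THI means and the late-gestation PC1 score are mapped onto the
#' dimensionless interval \[-1, 1\] before entering the reaction-norm models.
#' `thi_scaling()` returns the anchors used for weekly THI (17 and 72);
#' `pc1_scaling()` the anchors used for the PC1 score (-15 and 11).
#'
#' @return A list with elements `min_val` and `max_val`.
#' @export
thi_scaling <- function() list(min_val = 17, max_val = 72)

#' @rdname thi_scaling
#' @export
pc1_scaling <- function() list(min_val = -15, max_val = 11)

#' Scale a heat-load covariate to \[-1, 1\]
#'
#' Affine map `-1 + 2 (v - min) / (max - min)`. Values outside the anchor
#' range are clamped to -1 or 1 rather than extrapolated, so that reaction
#' norms are only ever evaluated inside the gradient over which they are
#' estimated.
#'
#' @param value Numeric vector on the original scale.
#' @param spec A list with `min_val` and `max_val` (see [thi_scaling()]), or
#'   `NULL` to pass `min_val`/`max_val` directly.
#' @param min_val,max_val Scalar anchors; used when `spec` is `NULL`.
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' scale_covariate(c(17, 44.5, 72), thi_scaling())  # -1, 0, 1
#' @export
scale_covariate <- function(value, spec = NULL, min_val = NULL, max_val = NULL) {
  if (!is.null(spec)) {
    min_val <- spec$min_val
    max_val <- spec$max_val
  }
  stopifnot(is.numeric(min_val), is.numeric(max_val), length(min_val) == 1L,
            length(max_val) == 1L, max_val > min_val)
  s <- -1 + 2 * (value - min_val) / (max_val - min_val)
  pmin(1, pmax(-1, s))
}

#' Invert the covariate scaling (without clamping)
#'
#' @inheritParams scale_covariate
#' @param scaled Numeric vector on the \[-1, 1\] scale.
#' @return Numeric vector on the original scale.
#' @export
unscale_covariate <- function(scaled, spec = NULL, min_val = NULL, max_val = NULL) {
  if (!is.null(spec)) {
    min_val <- spec$min_val
    max_val <- spec$max_val
  }
  min_val + (scaled + 1) / 2 * (max_val - min_val)
}
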