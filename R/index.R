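#' Constants of the protection index
#'
#' The composite index multiplies a width-based wave-attenuation factor, a
#' biomass-based frontal-barrier factor and greenness (NDVI), scaled by `S`.
#' Defaults follow the field-calibrated attenuation rate of 0.29 per km of
#' mangrove belt, the allometric biomass exponent 2.55 (biomass ~ h^2.55 for
#' stands up to ~10 m, where breast-height diameter grows roughly linearly
#' with height), a 10 m height cap above which the barrier factor saturates
#' at 1, and a display scale of 1000.
#'
#' @param rate attenuation rate constant, per km.
#' @param exponent biomass allometric exponent.
#' @param cap height cap in metres.
#' @param scale index scale `S`.
#' @return object of class `index_constants`.
#' @export
index_constants <- function(rate = 0.29, exponent = 2.55, cap = 10,
                            scale = 1000) {
  if (any(c(rate, exponent, cap, scale) <= 0))
    stop("index constants must be strictly positive")
  structure(list(rate = rate, exponent = exponent, cap = cap, scale = scale),
            class = "index_constants")
}

#' Wave-attenuation factor from belt width
#'
#' `A = 1 - exp(-rate * W)` with `W` in kilometres: 0 at zero width,
#' saturating towards 1 for very wide belts. At the default rate the decay
#' half-width is `log(2)/0.29 ~ 2.4 km` and roughly three quarters of the
#' attenuation is reached near 4.6 km.
#'
#' @param width_km belt width in km (vectorized, must be >= 0).
#' @param rate attenuation rate per km.
#' @return attenuation factor in `[0, 1)`.
#' @export
attenuation <- function(width_km, rate = 0.29) {
  if (any(width_km < 0)) stop("domain error: width must be >= 0")
  1 - exp(-rate * width_km)
}

#' Biomass barrier factor from canopy height
#'
#' `B = (h / cap)^exponent` for `h <= cap` and 1 above the cap — a
#' conservative saturation, since the linear diameter-height allometry
#' underlying the exponent holds only for stands up to about the cap height.
#' Continuous and non-decreasing in `h`.
#'
#' @param height_m canopy height in metres (vectorized, must be >= 0).
#' @param exponent allometric exponent.
#' @param cap saturation height in metres.
#' @return barrier factor in `[0, 1]`.
#' @export
biomass_barrier <- function(height_m, exponent = 2.55, cap = 10) {
  if (any(height_m < 0)) stop("domain error: height must be >= 0")
  pmin((height_m / cap)^exponent, 1)
}

#' Pixel NDVI
#'
#' `(NIR - red) / (NIR + red)`; pairs whose sum is not positive are
#' undefined and return NA (nodata).
#'
#' @param nir,red reflectances in `[0, 1]` (vectorized).
#' @return NDVI in `[-1, 1]`, NA where undefined.
#' @export
ndvi_pixel <- function(nir, red) {
  if (any(nir < 0 | nir > 1 | red < 0 | red > 1, na.rm = TRUE))
    stop("domain error: reflectances must lie in [0, 1]")
  den <- nir + red
  ifelse(is.na(den) | den <= 0, NA_real_, (nir - red) / den)
}

#' Composite protection index
#'
#' `MCPI = A * B * NDVI * S`; zero whenever any factor is zero.
#'
#' @param a attenuation factor in `[0, 1)`.
#' @param b barrier factor in `[0, 1]`.
#' @param ndvi greenness in `[0, 1]` (clip negative NDVI to 0 upstream).
#' @param scale the index scale `S`.
#' @return index in `[0, S]`.
#' @export
mcpi_score <- function(a, b, ndvi, scale = 1000) {
  if (any(a < 0 | a >= 1)) stop("domain error: A must lie in [0, 1)")
  if (any(b < 0 | b > 1)) stop("domain error: B must lie in [0, 1]")
  if (any(ndvi < 0 | ndvi > 1)) stop("domain error: NDVI must lie in [0, 1]")
  a * b * ndvi * scale
}

#' Fill protection-index columns on region records
#'
#' Adds (or recomputes — the operation is idempotent) the columns `a`, `b`
#' and `mcpi` from `amw_m` (converted to km), `ach_m` and `ndvi`. Negative
#' NDVI, possible over water-contaminated pixels, is clipped to 0 so the
#' index stays non-negative; an optional pooled min-max rescaling of NDVI is
#' available instead.
#'
#' @param records data.frame with `amw_m`, `ach_m`, `ndvi`.
#' @param constants an [index_constants()].
#' @param rescale_ndvi min-max rescale NDVI across the records before use?
#' @return `records` with columns `a`, `b`, `mcpi` filled.
#' @export
enrich_records <- function(records, constants = index_constants(),
                           rescale_ndvi = FALSE) {
  need <- c("amw_m", "ach_m", "ndvi")
  if (!all(need %in% names(records)))
    stop("validation error: records must have columns ",
         paste(need, collapse = ", "))
  v <- records$ndvi
  if (rescale_ndvi) {
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
  }
  v <- pmin(pmax(v, 0), 1)
  records$a <- attenuation(records$amw_m / 1000, rate = constants$rate)
  records$b <- biomass_barrier(records$ach_m, exponent = constants$exponent,
                               cap = constants$cap)
  records$mcpi <- mcpi_score(records$a, records$b, v, scale = constants$scale)
  records
}

#' Distribution summary (quartiles, mean, sd, maximum)
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the standard deviation is the sample sd.
#'
#' @param values non-empty numeric vector.
#' @return one-row data.frame: `q1`, `median`, `q3`, `mean`, `sd`, `max`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty-domain error: no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(q1 = q[1], median = q[2], q3 = q[3],
             mean = mean(values),
             sd = if (length(values) > 1) stats::sd(values) else 0,
             max = max(values))
}
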