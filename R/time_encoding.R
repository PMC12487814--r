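#' Build a sinusoidal time-encoding specification
#'
#' The frequency ladder follows the transformer-style construction:
#' `w_i = 2*pi / 10000^(2*i/d)` for `i = 0 .. d/2 - 1`, applied to the
#' rescaled time `t' = t / minWavelength`. Each frequency contributes a
#' sine and a cosine coordinate, giving exactly `d` coordinates. The
#' fastest component therefore has period exactly `minWavelength` days;
#' the minimum wavelength should be set to the shortest biological
#' period of interest (1 day by default, so circadian-scale patterns
#' remain representable).
#'
#' @param d even embedding dimension (default 50).
#' @param minWavelength minimum wavelength in days (default 1).
#' @return A [TimeEncoding-class].
#' @export
timeEncoding <- function(d = 50, minWavelength = 1) {
  d <- as.integer(d)
  if (d < 2 || d %% 2 != 0) stop("time-encoding dimension d must be even and >= 2")
  i <- seq_len(d / 2) - 1
  methods::new("TimeEncoding", d = as.numeric(d),
               minWavelength = as.numeric(minWavelength),
               frequencies = 2 * pi / 10000^(2 * i / d))
}

#' Sinusoidally encode time points
#'
#' Maps each time `t` (days) to the `d`-vector
#' `[sin(w_0 t'), cos(w_0 t'), ..., sin(w_{d/2-1} t'), cos(w_{d/2-1} t')]`
#' with `t' = t / minWavelength`. All coordinates lie in `[-1, 1]`, the
#' map is smooth in `t`, and distinct times within the working range get
#' distinct encodings (low frequencies disambiguate the periodic fast
#' components).
#'
#' @param t numeric vector of times (days); must be finite.
#' @param spec a [TimeEncoding-class].
#' @return `length(t)` x `d` matrix.
#' @examples
#' spec <- timeEncoding(d = 4)
#' sinusoidalEncode(0, spec)        # 0 1 0 1
#' sinusoidalEncode(0.25, timeEncoding(d = 2))  # 1 0
#' @export
sinusoidalEncode <- function(t, spec) {
  stopifnot(methods::is(spec, "TimeEncoding"))
  if (any(!is.finite(t))) stop("time values must be finite")
  tp <- t / spec@minWavelength
  ang <- outer(tp, spec@frequencies)        # n x d/2
  out <- matrix(0, length(t), spec@d)
  out[, seq(1, spec@d, by = 2)] <- sin(ang)
  out[, seq(2, spec@d, by = 2)] <- cos(ang)
  out
}

#' One-hot encoding of a categorical factor
#'
#' Returns the identity-indicator matrix for an ordered level list, and
#' a helper to encode observed labels against it.
#'
#' @param levels character vector of levels, in the order that defines
#'   the encoding columns.
#' @return A list with `levels` and `matrix` (identity, one row per level).
#' @export
factorEncoding <- function(levels) {
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("factor levels must be unique")
  m <- diag(length(levels))
  dimnames(m) <- list(levels, levels)
  list(levels = levels, matrix = m)
}

#' Encode labels as one-hot rows
#'
#' @param labels character vector of observed labels.
#' @param levels ordered level list; labels outside it are an error.
#' @return `length(labels)` x `length(levels)` indicator matrix.
#' @export
oneHot <- function(labels, levels) {
  labels <- as.character(labels)
  idx <- match(labels, levels)
  if (anyNA(idx))
    stop(sprintf("label(s) not in level set: %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  m <- matrix(0, length(labels), length(levels))
  m[cbind(seq_along(labels), idx)] <- 1
  colnames(m) <- levels
  m
}
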