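# Boltzmann constant in kJ/mol/K
KB_KJ <- 0.0083144626

# kcal -> kJ
KCAL_TO_KJ <- 4.184

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the interval (-180, 180]
#'
#' @param x angles in degrees.
#' @return angles in degrees, wrapped to (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- 180
  w
}

# Derive an operation-specific substream seed so composed pipelines are
# reproducible regardless of call order; result stays below 2^31.
derive_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647L)
}

with_op_seed <- function(seed, op, code) {
  withr::with_seed(derive_seed(seed, op), code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
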