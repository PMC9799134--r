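#' @importFrom rlang .data
#' @importFrom stats aov coef cor.test lm median p.adjust pt qt quantile rnorm
#'   runif sd t.test AIC BIC setNames
#' @importFrom utils head tail
NULL

DEG <- 180 / pi

deg2rad <- function(x) x / DEG
rad2deg <- function(x) x * DEG

#' Wrap angles to (-180, 180]
#'
#' All angular differences in the package are expressed on this branch so that
#' small clockwise (positive) and counterclockwise (negative) deviations from a
#' target bearing are directly comparable.
#'
#' @param x Angles in degrees.
#' @return Angles wrapped to the interval (-180, 180].
#' @export
wrap_angle_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# bearing of (x, y) about the origin, degrees clockwise from straight ahead (+y)
bearing_deg <- function(x, y) rad2deg(atan2(x, y))

# linear-interpolation IQR (quantile type 7)
iqr_linear <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

# run `expr` under a temporary RNG state seeded with `seed` (NULL = inherit)
with_seed_or_inherit <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tibble constructor without validation overhead, for hot paths
fast_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}
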