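# Small 3-vector helpers used throughout. Points are length-3 numerics or
# n x 3 matrices, always in patient millimeters.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(a) sqrt(sum(a * a))

normalize3 <- function(a) {
  n <- norm3(a)
  if (n < 1e-12) abort("cannot normalize a near-zero vector", "degenerate_vector_error")
  a / n
}

as_point_matrix <- function(x, arg = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    abort(sprintf("'%s' must be an n x 3 numeric matrix of points (mm)", arg),
          "io_error")
  storage.mode(x) <- "double"
  unname(x)
}

# Quadratic (3-point) sub-sample refinement of a discrete peak. Returns the
# fractional offset in [-0.5, 0.5] of the true extremum from the center sample.
quad_refine <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < 1e-12) return(0)
  d <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, d))
}

wrap_angle <- function(theta) theta %% (2 * pi)

# smallest absolute circular difference a-b, result in [-pi, pi)
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d >= pi] <- d[d >= pi] - 2 * pi
  d
}
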