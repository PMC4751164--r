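# Analytic meshes used as curvature / radial-map oracles.

norm3 <- aorticroot:::norm3
cross3 <- aorticroot:::cross3
normalize3 <- aorticroot:::normalize3

# Icosphere: subdivided icosahedron projected onto a sphere of radius r.
make_icosphere <- function(subdiv = 4L, r = 10) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdiv)) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mid_env <- new.env()
    newv <- list()
    midpoint <- function(i, j) {
      k <- key(i, j)
      m <- mid_env[[k]]
      if (!is.null(m)) return(m)
      newv[[length(newv) + 1L]] <<- (v[i, ] + v[j, ]) / 2
      m <- nrow(v) + length(newv)
      mid_env[[k]] <- m
      m
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  surface_mesh(v, f)
}

# Tube mesh of radius r_fun(theta, z) around the z axis, open at both ends.
make_tube_mesh <- function(r_fun, z_lo = 0, z_hi = 40, dz = 0.5,
                           n_theta = 192L) {
  zs <- seq(z_lo, z_hi, by = dz)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  ns <- length(zs)
  zz <- rep(zs, times = n_theta)
  tt <- rep(th, each = ns)
  rr <- r_fun(tt, zz)
  V <- cbind(rr * cos(tt), rr * sin(tt), zz)
  vid <- function(i, j) (j - 1L) * ns + i
  i <- rep(seq_len(ns - 1L), times = n_theta)
  j <- rep(seq_len(n_theta), each = ns - 1L)
  jn <- (j %% n_theta) + 1L
  surface_mesh(V, rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, jn)),
                        cbind(vid(i, j), vid(i + 1L, jn), vid(i, jn))))
}

# Open saddle patch z = (x^2 - y^2) / 20 on a regular grid.
make_saddle_mesh <- function(half = 5, step = 0.25) {
  xs <- seq(-half, half, by = step)
  n <- length(xs)
  g <- expand.grid(x = xs, y = xs)
  V <- cbind(g$x, g$y, (g$x^2 - g$y^2) / 20)
  vid <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  surface_mesh(V, rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                        cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))))
}

straight_centerline <- function(z_lo = 0, z_hi = 40, by = 1) {
  cbind(0, 0, seq(z_lo, z_hi, by = by))
}

random_rigid <- function(seed, angle_deg = 30) {
  set.seed(seed)
  rigid_transform(rotation_about_axis(rnorm(3), angle_deg),
                  runif(3, -20, 20))
}
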