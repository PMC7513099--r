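# Frozen arbitrary-precision oracle values (50-digit mpmath besseli), used to
# pin down the log-domain Bessel path independently of base R's besselI.
bessel_oracle <- data.frame(
  order = c(0, 0.5, 2.5, 4, 10, 12, 3),
  kappa = c(1, 1, 10, 240, 1e3, 500, 1e5),
  log_i = c(0.23591435850717864869, -0.064351991073531798753,
            7.61505817170335168, 236.30786161619746116,
            995.57728428064997687, 495.82987030759619759,
            99993.324554984091464)
)

# Same oracle in the regimes where base besselI under/overflows and the
# uniform large-order expansion takes over.
bessel_oracle_extreme <- data.frame(
  order = c(249, 249, 249, 149.5, 49.5, 0, 5),
  kappa = c(4, 4e6, 2400, 40, 4, 1e6, 1e6),
  log_i = c(-955.91412342348132541, 3999991.472408912537,
            2382.2814979864022943, -152.01696120846990912,
            -112.12932292161920491, 999992.17330631281325,
            999992.173293812807)
)

vmf_oracle <- data.frame(
  K = c(10, 7, 5),
  kappa = c(240, 1000, 1e-8),
  log_c = c(223.57469125487622337, 984.7873638622838807, 3.2702890247105265951)
)

# Dense tensor quadrature (Simpson in the polar angle, periodic trapezoid in
# the azimuth) of the sphere-constrained Laplace integral for K = 3: the log
# of the surface integral of exp(-N/2 (theta - theta_hat)' H (theta -
# theta_hat)) over the radius-sqrt(3/R) sphere, with H = 4h Id and theta_hat
# placed at polar/azimuthal angles (phi0, psi0).  Entirely independent of the
# package's closed-form path.
quad_log_sphere_laplace <- function(N, R = 1, phi0 = 0, psi0 = 0,
                                    n_phi = 1601, n_psi = 1600) {
  K <- 3
  r <- sqrt(K / R)
  h <- R / K
  th_hat <- r * c(sin(phi0) * cos(psi0), sin(phi0) * sin(psi0), cos(phi0))
  phi <- seq(0, pi, length.out = n_phi)
  psi <- seq(0, 2 * pi, length.out = n_psi + 1)[-(n_psi + 1)]
  sp <- sin(phi)
  cp <- cos(phi)
  acc <- numeric(n_phi)
  for (j in seq_along(psi)) {
    d2 <- (r * sp * cos(psi[j]) - th_hat[1])^2 +
      (r * sp * sin(psi[j]) - th_hat[2])^2 +
      (r * cp - th_hat[3])^2
    acc <- acc + exp(-2 * N * h * d2)
  }
  w <- c(1, rep(c(4, 2), (n_phi - 3) / 2), 4, 1) / 3 * (pi / (n_phi - 1))
  log(sum(w * acc * r^2 * sp) * (2 * pi / n_psi))
}

# Data vector whose K-bin histogram over [0, 1] has exactly equal counts.
equal_count_data <- function(N, K) {
  stopifnot(N %% K == 0)
  centers <- (seq_len(K) - 0.5) / K
  x <- rep(centers, each = N / K)
  x[1] <- 0
  x[length(x)] <- 1
  x
}
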