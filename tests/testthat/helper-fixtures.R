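# shared helpers: small models and geometry builders used across test files

# conversion factor mu_B/h in MHz/mT, recomputed from the defining constants
# so that field-position tests are independent of the package's internals
MHZ_PER_MT_REF <- 9.2740100783e-24 / 6.62607015e-34 * 1e-9

# one-component model on a reduced band set, cheap to simulate
quick_model <- function(g_xx = 2.008, weights = 1, g_yy = 2.006,
                        g_zz = 2.0022, A = c(14, 14, 100),
                        bands = c(X = 9.7671, J = 262.8436),
                        alw_xx = 20, alw_yy = 20, alw_zz = 18) {
  multicomponent_model(
    g_xx = g_xx, weights = weights, g_yy = g_yy, g_zz = g_zz, A = A,
    alw = data.frame(band = names(bands), frequency_GHz = unname(bands),
                     alw_xx = alw_xx, alw_yy = alw_yy, alw_zz = alw_zz))
}

# a water donating one H-bond to `acc`: O...H distance r, cos(theta) ct
make_bonded_water <- function(acc, r = 1.8, ct = -0.95,
                              direction = c(1, 0, 0)) {
  v <- direction / sqrt(sum(direction^2))
  H1 <- acc + r * v
  st <- sqrt(1 - ct^2)
  perp <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- perp - sum(perp * v) * v
  t1 <- t1 / sqrt(sum(t1^2))
  m <- ct * (-v) + st * t1
  Od <- H1 + 0.97 * m
  t2 <- v - sum(v * m) * m
  t2 <- t2 / sqrt(sum(t2^2))
  m2 <- cos(104.5 * pi / 180) * (-m) + sin(104.5 * pi / 180) * t2
  H2 <- Od + 0.97 * m2
  rbind(Od, H1, H2)
}

# a water at O-O distance d whose hydrogens point away from the acceptor
make_free_water <- function(acc, d = 4.5, direction = c(0, 1, 0)) {
  u <- direction / sqrt(sum(direction^2))
  Ow <- acc + d * u
  perp <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- perp - sum(perp * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  h1 <- cos(0.4) * u + sin(0.4) * t1
  t2 <- u - sum(u * h1) * h1
  t2 <- t2 / sqrt(sum(t2^2))
  h2 <- cos(104.5 * pi / 180) * h1 + sin(104.5 * pi / 180) * t2
  rbind(Ow, Ow + 0.97 * h1, Ow + 0.97 * h2)
}

# brute-force minimum distance over all 27 periodic images
image_min_dist <- function(a, b, L) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * L
  min(sqrt(rowSums((matrix(b, 27, 3, byrow = TRUE) + shifts -
                      matrix(a, 27, 3, byrow = TRUE))^2)))
}

random_orientations <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
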