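# Shared fixtures built in code. The climate stack is deterministic given
# its params, so one cached copy serves many tests.

ts_small_params <- function(...) {
  args <- list(grid_shape = c(24L, 24L),
               lat_range = c(40, 42), lon_range = c(-84, -82),
               n_records = c(pre = 120, post = 100),
               seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_params, args)
}

.ts_cache <- new.env(parent = emptyenv())

ts_small_stack <- function() {
  if (is.null(.ts_cache$small_stack))
    .ts_cache$small_stack <- gen_climate_stack(ts_small_params())
  .ts_cache$small_stack
}

ts_default_stack <- function() {
  if (is.null(.ts_cache$default_stack))
    .ts_cache$default_stack <- gen_climate_stack(synth_params(seed = 5L))
  .ts_cache$default_stack
}

# uniform random record locations over the in-mask cells of a stack
ts_random_sites <- function(stack, n) {
  g <- stack$grid
  idx <- sample(which(stack$mask), n, replace = TRUE)
  row <- ((idx - 1L) %% g$nrow) + 1L
  col <- ((idx - 1L) %/% g$nrow) + 1L
  cs <- g$cellsize
  data.frame(lon = g$xll + (col - 1L) * cs + stats::runif(n) * cs,
             lat = g$yll + (g$nrow - row) * cs + stats::runif(n) * cs,
             elev_m = stack$dem[cbind(row, col)])
}

# independent dense evaluation of the spatial mixed-model log-likelihood:
# builds the full covariance and calls the multivariate normal density
# by explicit inversion (no Cholesky shortcuts shared with the package)
ts_dense_loglik <- function(y, X, year, coords, beta, s2y, s2r, rho,
                            jitter = 1e-8) {
  n <- length(y)
  D <- sqrt(outer(coords[, 1], coords[, 1], `-`)^2 +
            outer(coords[, 2], coords[, 2], `-`)^2 +
            (if (ncol(coords) > 2)
               outer(coords[, 3], coords[, 3], `-`)^2 else 0))
  Cm <- exp(-D / rho)
  diag(Cm) <- diag(Cm) + jitter
  V <- s2y * (outer(year, year, `==`) + 0) + s2r * Cm
  r <- y - X %*% beta
  Vi <- solve(V)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  drop(-0.5 * n * log(2 * pi) - 0.5 * ld - 0.5 * t(r) %*% Vi %*% r)
}

# random 3-D coordinates for spline tests
ts_tps_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(lat = runif(n, 40, 44), lon = runif(n, -84, -80),
        elev = runif(n, 0, 1500))
}

# independent dense solve of the bordered thin-plate system, assembled and
# solved in one shot (no QR/eigen reduction), same kernel and coordinate
# standardization contract
ts_tps_oracle <- function(coords, y, lambda) {
  n <- nrow(coords)
  Xs <- scale(coords)
  D <- as.matrix(dist(Xs))
  K <- -D
  Tm <- cbind(1, Xs)
  M <- rbind(cbind(K + n * lambda * diag(n), Tm),
             cbind(t(Tm), matrix(0, 4, 4)))
  sol <- solve(M, c(y, rep(0, 4)))
  list(c = sol[1:n], d = sol[(n + 1):(n + 4)],
       predict = function(newx) {
         Ns <- sweep(sweep(as.matrix(newx), 2,
                           attr(Xs, "scaled:center")), 2,
                     attr(Xs, "scaled:scale"), "/")
         Dn <- sqrt(outer(Ns[, 1], Xs[, 1], `-`)^2 +
                    outer(Ns[, 2], Xs[, 2], `-`)^2 +
                    outer(Ns[, 3], Xs[, 3], `-`)^2)
         drop(-Dn %*% sol[1:n] + cbind(1, Ns) %*% sol[(n + 1):(n + 4)])
       })
}
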