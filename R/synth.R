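#' Parameters for the synthetic study system
#'
#' Defines the generative model used by [gen_climate_stack()] and
#' [gen_specimens()]: a gridded climate with a dominant latitudinal gradient,
#' decadal layers spanning a century split at a warming cutoff, and specimen
#' traits (log snout--vent length and breeding Julian day) driven by scaled
#' frost-free days (FFD) and precipitation with a collection-year random
#' intercept and spatially autocorrelated residuals.
#'
#' Trait coefficients act on centred-and-scaled climate, so they share units
#' with the fitted model coefficients. `sigma_year` and `sigma_resid` are
#' named vectors with components `size` (log-mm scale) and `phen` (days).
#'
#' @param grid_shape `c(rows, cols)` of the climate grid.
#' @param cell_size cell edge in degrees (default 5 arc-minutes).
#' @param lat_range,lon_range extent of the grid, degrees (south/west corner
#'   is `c(lat_range[1], lon_range[1])`).
#' @param decades integer vector of decade start years; each decade covers
#'   `start..start+9`.
#' @param cutoff_year last calendar year of the "pre" period.
#' @param beta_size_f,beta_size_m length-3 coefficients `(ffd, precip,
#'   ffd:precip)` on log-SVL for females / males.
#' @param beta_phen length-2 coefficients `(ffd, precip)` on Julian day.
#' @param intercept_size_f,intercept_size_m,intercept_phen trait intercepts.
#' @param sigma_year,sigma_resid named SDs `c(size=, phen=)` of the year
#'   random intercept and of the spatially correlated residual.
#' @param spatial_range exponential-correlation range rho, degrees.
#' @param climate_shift named amplitudes `c(temperature=, ffd=,
#'   precipitation=)` of the additive post-cutoff shift fields. The shift is
#'   spatially uneven (a smooth random pattern): temperature and FFD shift
#'   by `amplitude * u` with `u` in (0, 1) (warming everywhere, unevenly),
#'   precipitation by `amplitude * v` with `v` in (-1, 1) (some areas drier,
#'   some wetter).
#' @param temp_ffd_target_r target cell-wise correlation between the
#'   temperature and FFD fields.
#' @param n_records named record counts `c(pre=, post=)`.
#' @param contaminant_frac fraction of records given nonbreeding-season dates.
#' @param p_female probability a record is female.
#' @param seed integer RNG seed; all generation is reproducible from it.
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(grid_shape = c(48L, 48L),
                         cell_size = 5 / 60,
                         lat_range = c(40, 40 + grid_shape[1] * cell_size),
                         lon_range = c(-84, -84 + grid_shape[2] * cell_size),
                         decades = seq(1901, 1991, by = 10),
                         cutoff_year = 1960,
                         beta_size_f = c(ffd = 0, precip = 0.112,
                                         inter = 0.045),
                         beta_size_m = c(ffd = 0.041, precip = 0.008,
                                         inter = -0.004),
                         beta_phen = c(ffd = -42.403, precip = -1.219),
                         intercept_size_f = log(46),
                         intercept_size_m = log(42),
                         intercept_phen = 150,
                         sigma_year = c(size = 0.032, phen = 14),
                         sigma_resid = c(size = 0.146, phen = 28),
                         spatial_range = 1,
                         climate_shift = c(temperature = 1.6, ffd = 16,
                                           precipitation = 80),
                         temp_ffd_target_r = 0.87,
                         n_records = c(pre = 679, post = 585),
                         contaminant_frac = 0.05,
                         p_female = 0.38,
                         seed = 1L) {
  # YAML/JSON configs deliver named lists where the API takes named vectors
  for (nm in c("sigma_year", "sigma_resid", "climate_shift", "n_records",
               "beta_size_f", "beta_size_m", "beta_phen"))
    assign(nm, unlist(get(nm)))
  p <- list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
            lat_range = lat_range, lon_range = lon_range,
            decades = as.integer(decades), cutoff_year = as.integer(cutoff_year),
            beta_size_f = beta_size_f, beta_size_m = beta_size_m,
            beta_phen = beta_phen,
            intercept_size_f = intercept_size_f,
            intercept_size_m = intercept_size_m,
            intercept_phen = intercept_phen,
            sigma_year = sigma_year, sigma_resid = sigma_resid,
            spatial_range = spatial_range, climate_shift = climate_shift,
            temp_ffd_target_r = temp_ffd_target_r,
            n_records = n_records, contaminant_frac = contaminant_frac,
            p_female = p_female, seed = as.integer(seed))
  stopifnot(all(p$grid_shape > 0), p$cell_size > 0,
            p$contaminant_frac >= 0, p$contaminant_frac < 0.5,
            all(p$sigma_year >= 0), all(p$sigma_resid >= 0),
            p$spatial_range > 0,
            all(c("size", "phen") %in% names(p$sigma_year)),
            all(c("size", "phen") %in% names(p$sigma_resid)),
            all(c("pre", "post") %in% names(p$n_records)))
  if (abs(p$temp_ffd_target_r) >= 1)
    stop("temp_ffd_target_r must satisfy |r| < 1")
  if (abs(diff(p$lat_range) - p$grid_shape[1] * p$cell_size) > p$cell_size ||
      abs(diff(p$lon_range) - p$grid_shape[2] * p$cell_size) > p$cell_size)
    stop("lat_range/lon_range extent must equal grid_shape * cell_size")
  if (!any(p$decades <= p$cutoff_year) ||
      !any(p$decades + 9L > p$cutoff_year))
    stop("decades must cover both sides of cutoff_year")
  class(p) <- "synth_params"
  p
}

decade_table <- function(params) {
  data.frame(label = sprintf("%d-%d", params$decades, params$decades + 9L),
             start = params$decades, end = params$decades + 9L,
             period = ifelse(params$decades + 9L <= params$cutoff_year,
                             "pre", "post"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic decadal climate stack
#'
#' Temperature and FFD are built from a shared latent latitudinal-gradient
#' field plus independent smooth noise; the mixing weight is calibrated so
#' their empirical cell-wise correlation inside the mask lands within 0.03 of
#' `temp_ffd_target_r`. Precipitation gets its own gradient and noise with a
#' weak shared component. Each decade receives a small independent smooth
#' anomaly; decades ending after `cutoff_year` are additionally shifted by
#' `climate_shift`. An elliptical range mask and a synthetic DEM are attached.
#'
#' @param params a [synth_params()] object.
#' @return object of class `climate_stack`: list with `grid`, `mask`,
#'   `decades` (data.frame), `values` (`values[[variable]][[decade label]]`
#'   matrices), and `dem`.
#' @export
gen_climate_stack <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  nr <- params$grid_shape[1]; nc <- params$grid_shape[2]
  grid <- trait_grid(nr, nc, xll = params$lon_range[1],
                     yll = params$lat_range[1], cellsize = params$cell_size)

  cc <- grid_centers(grid)
  latm <- matrix(cc$lat, nr, nc, byrow = TRUE)
  lonm <- matrix(cc$lon, nr, nc, byrow = TRUE)
  # elliptical range mask covering most of the grid
  lat_ext <- range(latm); lon_ext <- range(lonm)
  mask <- ((latm - mean(lat_ext)) / (diff(lat_ext) * 0.56))^2 +
    ((lonm - mean(lon_ext)) / (diff(lon_ext) * 0.56))^2 <= 1

  # latent gradient: colder / fewer frost-free days northward, standardized
  g <- -(latm - mean(latm)) / stats::sd(latm)
  n_t <- smooth_field(nr, nc, 2)
  n_f <- smooth_field(nr, nc, 2)

  # calibrate mixing weight w so cor(temp, ffd) inside mask hits the target;
  # smooth fields have few effective degrees of freedom, so the nominal
  # w = r is adjusted by bisection on the empirical correlation
  target <- params$temp_ffd_target_r
  mix <- function(w) {
    t_std <- sqrt(w) * g + sqrt(1 - w) * n_t
    f_std <- sqrt(w) * g + sqrt(1 - w) * n_f
    list(t = t_std, f = f_std, r = stats::cor(t_std[mask], f_std[mask]))
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  w <- target^2  # starting guess: both fields share sqrt(w) of the latent
  m <- mix(w)
  for (it in seq_len(40)) {
    if (abs(m$r - target) <= 0.03) break
    if (m$r < target) lo <- w else hi <- w
    w <- (lo + hi) / 2
    m <- mix(w)
  }

  temp_base <- 9 + 6 * m$t
  ffd_base <- 180 + 45 * m$f
  # precipitation: own smooth structure, weak link to the gradient
  p_std <- sqrt(0.1) * g + sqrt(0.9) * smooth_field(nr, nc, 2)
  prec_base <- 950 + 160 * p_std

  dt <- decade_table(params)
  base <- list(temperature = temp_base, ffd = ffd_base,
               precipitation = prec_base)
  # smooth spatial patterns modulating the post-cutoff shift: in (0,1) for
  # warming variables, in (-1,1) for precipitation
  shift_field <- list(
    temperature = stats::pnorm(smooth_field(nr, nc, 3)),
    ffd = stats::pnorm(smooth_field(nr, nc, 3)),
    precipitation = 2 * stats::pnorm(smooth_field(nr, nc, 3)) - 1
  )
  values <- lapply(names(base), function(v) {
    lay <- lapply(seq_len(nrow(dt)), function(d) {
      x <- base[[v]]
      if (dt$period[d] == "post")
        x <- x + params$climate_shift[[v]] * shift_field[[v]]
      if (v == "ffd") x <- pmin(pmax(x, 0), 366)
      if (v == "precipitation") x <- pmax(x, 1)
      x[!mask] <- NA
      x
    })
    names(lay) <- dt$label
    lay
  })
  names(values) <- names(base)

  dem <- synthetic_dem(grid)
  dem[!mask] <- NA

  structure(list(grid = grid, mask = mask, decades = dt, values = values,
                 dem = dem),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d x %d cells (%d in mask), %d decades, vars: %s\n",
              x$grid$nrow, x$grid$ncol, sum(x$mask), nrow(x$decades),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

# date from (year, day-of-year), clamping day 366 in non-leap years
date_from_julian <- function(year, jday) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  jday <- pmin(jday, ifelse(leap, 366L, 365L))
  as.Date(jday - 1L, origin = as.Date(sprintf("%d-01-01", year)))
}

#' Generate synthetic specimen records with known ground truth
#'
#' Records are placed uniformly over in-mask cells (uniform position within
#' the cell), assigned a sex, a collection year uniform within its period,
#' and climate from their decade's layers. Traits follow
#' `log SVL = intercept_sex + beta_sex . (sFFD, sPrec, sFFD*sPrec) + u_year + e`
#' and `Julian day = intercept + beta_phen . (sFFD, sPrec) + u_year + e`,
#' where `u_year` is a per-year intercept (SD `sigma_year`) and `e` a
#' spatially correlated Gaussian residual, `cor(e_i, e_j) =
#' exp(-d_ij / spatial_range)` with `d` the horizontal (lat, lon) Euclidean
#' distance in degrees. Scaled climate uses the mean/SD over the full
#' generated record set; the transform is stored in the truth. A fraction
#' `contaminant_frac` of records is re-dated 90--180 days after its breeding
#' expectation and flagged as nonbreeding in the truth.
#'
#' @param params a [synth_params()] object.
#' @param stack a [gen_climate_stack()] result covering the sampling extent.
#' @return list with `specimens` (data.frame: id, sex, svl_mm, date,
#'   julian_day, lat, lon, elev_m, year, period) and `truth` (class
#'   `synth_truth`): coefficients, variance components, year effects,
#'   residuals, noiseless linear predictors, climate scaling transforms, and
#'   the nonbreeding flag.
#' @export
gen_specimens <- function(params, stack) {
  stopifnot(inherits(params, "synth_params"), inherits(stack, "climate_stack"))
  if (!any(stack$mask)) stop("empty range mask: nothing to sample")
  set.seed(params$seed + 1L)

  dt <- stack$decades
  n_pre <- params$n_records[["pre"]]; n_post <- params$n_records[["post"]]
  n <- n_pre + n_post
  period <- rep(c("pre", "post"), c(n_pre, n_post))
  pre_years <- min(dt$start):params$cutoff_year
  post_years <- (params$cutoff_year + 1L):max(dt$end)
  year <- integer(n)
  if (n_pre > 0) {
    year[period == "pre"] <- c(pre_years,
      sample(pre_years, max(0L, n_pre - length(pre_years)),
             replace = TRUE))[seq_len(n_pre)]
  }
  if (n_post > 0) {
    year[period == "post"] <- c(post_years,
      sample(post_years, max(0L, n_post - length(post_years)),
             replace = TRUE))[seq_len(n_post)]
  }

  idx_mask <- which(stack$mask)          # column-major cell indices
  pick <- sample(idx_mask, n, replace = TRUE)
  row <- ((pick - 1L) %% stack$grid$nrow) + 1L
  col <- ((pick - 1L) %/% stack$grid$nrow) + 1L
  cs <- stack$grid$cellsize
  lon <- stack$grid$xll + (col - 1L) * cs + stats::runif(n) * cs
  lat <- stack$grid$yll + (stack$grid$nrow - row) * cs + stats::runif(n) * cs
  elev <- stack$dem[cbind(row, col)]
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")

  dec_idx <- findInterval(year, dt$start)
  ffd <- prec <- numeric(n)
  for (d in unique(dec_idx)) {
    sel <- dec_idx == d
    ffd[sel] <- stack$values$ffd[[d]][cbind(row[sel], col[sel])]
    prec[sel] <- stack$values$precipitation[[d]][cbind(row[sel], col[sel])]
  }
  ffd_tr <- c(mean = mean(ffd), sd = stats::sd(ffd))
  prec_tr <- c(mean = mean(prec), sd = stats::sd(prec))
  sffd <- (ffd - ffd_tr["mean"]) / ffd_tr["sd"]
  sprec <- (prec - prec_tr["mean"]) / prec_tr["sd"]

  years_all <- sort(unique(year))
  u_size <- stats::rnorm(length(years_all), 0, params$sigma_year[["size"]])
  u_phen <- stats::rnorm(length(years_all), 0, params$sigma_year[["phen"]])
  names(u_size) <- names(u_phen) <- years_all
  yi <- as.character(year)

  e_size <- spatial_noise(lat, lon, params$spatial_range,
                          params$sigma_resid[["size"]])
  e_phen <- spatial_noise(lat, lon, params$spatial_range,
                          params$sigma_resid[["phen"]])

  X3 <- cbind(sffd, sprec, sffd * sprec)
  mu_size <- ifelse(sex == "female",
                    params$intercept_size_f + X3 %*% params$beta_size_f,
                    params$intercept_size_m + X3 %*% params$beta_size_m)
  mu_size <- drop(mu_size)
  log_svl <- mu_size + u_size[yi] + e_size
  mu_phen <- params$intercept_phen +
    drop(cbind(sffd, sprec) %*% params$beta_phen)
  jd <- mu_phen + u_phen[yi] + e_phen

  n_bad <- round(params$contaminant_frac * n)
  nonbreeding <- logical(n)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    nonbreeding[bad] <- TRUE
    jd[bad] <- jd[bad] + stats::runif(n_bad, 90, 180)
  }
  jd <- pmin(pmax(round(jd), 1L), 366L)

  specimens <- data.frame(
    id = sprintf("TS%05d", seq_len(n)),
    sex = sex,
    svl_mm = round(exp(log_svl), 2),
    date = date_from_julian(year, jd),
    julian_day = as.integer(jd),
    lat = lat, lon = lon, elev_m = round(elev, 1),
    year = year,
    period = period,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    params = params,
    beta_size_f = params$beta_size_f, beta_size_m = params$beta_size_m,
    beta_phen = params$beta_phen,
    intercepts = c(size_f = params$intercept_size_f,
                   size_m = params$intercept_size_m,
                   phen = params$intercept_phen),
    sigma_year = params$sigma_year, sigma_resid = params$sigma_resid,
    spatial_range = params$spatial_range,
    year_effects = list(size = u_size, phen = u_phen),
    residuals = list(size = e_size, phen = e_phen),
    mu = list(size = mu_size, phen = mu_phen),
    scaling = list(ffd = ffd_tr, precip = prec_tr),
    climate = data.frame(ffd = ffd, precipitation = prec,
                         scaled_ffd = sffd, scaled_precip = sprec),
    nonbreeding = nonbreeding
  ), class = "synth_truth")

  list(specimens = specimens, truth = truth)
}

# zero-mean Gaussian vector with exponential spatial correlation over
# horizontal Euclidean distance; tiny diagonal jitter keeps the Cholesky
# stable when points nearly coincide
spatial_noise <- function(lat, lon, range, sd) {
  n <- length(lat)
  if (sd == 0) return(numeric(n))
  d <- as.matrix(stats::dist(cbind(lat, lon)))
  C <- exp(-d / range)
  L <- chol(C + diag(1e-8, n))
  drop(crossprod(L, stats::rnorm(n))) * sd
}

#' Write synthetic outputs to disk
#'
#' Specimens go to CSV, climate layers and the DEM to ESRI ASCII grids (one
#' file per variable per decade), ground truth to JSON.
#'
#' @param specimens,truth from [gen_specimens()].
#' @param stack from [gen_climate_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic <- function(specimens, truth, stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "specimens.csv")
  utils::write.csv(specimens, files, row.names = FALSE)
  for (v in names(stack$values)) {
    for (d in names(stack$values[[v]])) {
      f <- file.path(dir, sprintf("%s_%s.asc", v, d))
      write_ascii_grid(stack$values[[v]][[d]], stack$grid, f)
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "dem.asc")
  write_ascii_grid(stack$dem, stack$grid, f)
  fm <- file.path(dir, "mask.asc")
  write_ascii_grid(stack$mask + 0, stack$grid, fm)
  ft <- file.path(dir, "truth.json")
  tr <- truth
  tr$params <- unclass(tr$params)
  jsonlite::write_json(unclass(tr), ft, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(files, f, fm, ft))
}
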