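# End-to-end orchestration: simulate/ingest -> season filter -> historic
# climate-trait models -> bootstrap trait maps -> change-vs-climate GLS.
# Every stage persists its artifacts under the output directory and the run
# ends with a manifest of configuration, counts, checksums and timings.

#' Read a climate stack from a directory of ESRI ASCII grids
#'
#' Expects files `<variable>_<start>-<end>.asc` for variables temperature,
#' ffd, precipitation, plus `dem.asc` and `mask.asc` (nonzero = in range),
#' as written by [write_synthetic()].
#'
#' @param dir directory path.
#' @param cutoff_year used to label decades pre/post.
#' @return a `climate_stack`.
#' @export
read_climate_stack <- function(dir, cutoff_year = 1960) {
  files <- list.files(dir, pattern = "^(temperature|ffd|precipitation)_[0-9]{4}-[0-9]{4}\\.asc$")
  if (length(files) == 0) stop("no climate layers found in ", dir)
  meta <- do.call(rbind, lapply(files, function(f) {
    m <- regmatches(f, regexec("^([a-z]+)_([0-9]{4})-([0-9]{4})\\.asc$", f))[[1]]
    data.frame(file = f, var = m[2], start = as.integer(m[3]),
               end = as.integer(m[4]), stringsAsFactors = FALSE)
  }))
  starts <- sort(unique(meta$start))
  dt <- data.frame(label = sprintf("%d-%d", starts, starts + 9L),
                   start = starts, end = starts + 9L,
                   period = ifelse(starts + 9L <= cutoff_year, "pre", "post"),
                   stringsAsFactors = FALSE)
  first <- read_ascii_grid(file.path(dir, meta$file[1]))
  grid <- first$grid
  maskf <- file.path(dir, "mask.asc")
  mask <- if (file.exists(maskf)) {
    mg <- read_ascii_grid(maskf)
    !is.na(mg$values) & mg$values != 0
  } else !is.na(first$values)
  values <- list()
  for (v in unique(meta$var)) {
    values[[v]] <- list()
    for (i in seq_len(nrow(dt))) {
      f <- meta$file[meta$var == v & meta$start == dt$start[i]]
      if (length(f) != 1) stop("missing layer: ", v, " ", dt$label[i])
      g <- read_ascii_grid(file.path(dir, f))
      if (!grid_same(g$grid, grid)) stop("grid mismatch in ", f)
      values[[v]][[dt$label[i]]] <- g$values
    }
  }
  demf <- file.path(dir, "dem.asc")
  dem <- if (file.exists(demf)) read_ascii_grid(demf)$values
         else matrix(0, grid$nrow, grid$ncol)
  structure(list(grid = grid, mask = mask, decades = dt, values = values,
                 dem = dem),
            class = "climate_stack")
}

#' Default pipeline configuration
#'
#' Every analysis constant is a named key: warming cutoff 1960, 1-degree
#' latitude bands, 100 bootstrap replicates, 484 change points, delta AICc
#' support threshold 2, 5-arc-minute grid. Override any subset via `...` or
#' supply a YAML/JSON file to [run_pipeline()].
#'
#' @param ... overrides.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = "traitshift_run",
    seed = 1L,
    simulate = TRUE,          # or FALSE with records/climate_dir paths set
    records = NULL,
    climate_dir = NULL,
    synth = list(),           # synth_params() overrides when simulating
    cutoff_year = 1960,
    band_width = 1,
    gap_days = 45,
    min_band = 4,
    B = 100,
    n_points = 484,
    delta_aicc = 2,
    weight_mode = "precision",
    scale_coords = FALSE,
    lmm_coords = c("lat", "lon", "elev_m"),
    responses_lmm = c("log_svl_female", "log_svl_male", "julian_day"),
    responses_map = c("svl_female", "svl_male", "julian_day")
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) simulate or load specimen records and decadal
#' climate; (2) validate records and split breeding from nonbreeding
#' collections per latitude band; (3) attach per-record climate, collinearity
#' diagnostics, proportional climate change; (4) fit the five-candidate
#' spatial mixed model set per response on pre-cutoff data, with AICc
#' selection/averaging (nonbreeding records are excluded from the phenology
#' response only); (5) bootstrap thin-plate-spline maps pre/post per response
#' and CI-overlap change maps; (6) sample change points and fit the
#' averaged polynomial change GLS per response (Table-1 analog). Each stage
#' persists artifacts under `out_dir` and failures abort with the stage name.
#'
#' @param config a [pipeline_config()], or a path to a YAML/JSON file of
#'   overrides.
#' @return a run manifest (list): the config, record/pixel counts after each
#'   filter, per-stage timings, md5 checksums of every persisted artifact,
#'   and the package version — plus the in-memory stage results (`historic`,
#'   `maps`, `gls`, `collinearity`) for interactive use.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   counts = list(), timings = list(), files = character(0))
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$timings[[name]] <<- as.numeric(difftime(Sys.time(), ts,
                                                     units = "secs"))
    res
  }

  # -- stage 1: data ---------------------------------------------------
  data_dir <- file.path(out, "data")
  stk <- stage("data", {
    if (isTRUE(config$simulate)) {
      sp <- do.call(synth_params, c(config$synth,
                                    list(seed = config$seed,
                                         cutoff_year = config$cutoff_year)))
      stack <- gen_climate_stack(sp)
      gs <- gen_specimens(sp, stack)
      write_synthetic(gs$specimens, gs$truth, stack, data_dir)
      stack
    } else {
      if (is.null(config$records) || is.null(config$climate_dir))
        stop("simulate=FALSE needs 'records' and 'climate_dir' paths")
      dir.create(data_dir, showWarnings = FALSE)
      file.copy(config$records, file.path(data_dir, "specimens.csv"),
                overwrite = TRUE)
      read_climate_stack(config$climate_dir, config$cutoff_year)
    }
  })

  # -- stage 2: ingest + season split ----------------------------------
  season <- stage("ingest", {
    rd <- read_specimens(file.path(data_dir, "specimens.csv"),
                         cutoff_year = config$cutoff_year)
    manifest$counts$records_kept <- rd$n_kept
    manifest$counts$records_dropped <- rd$n_dropped
    sp <- split_breeding(rd$specimens, band_width = config$band_width,
                         gap_days = config$gap_days,
                         min_band = config$min_band)
    rec <- rd$specimens
    rec$season <- sp$season
    utils::write.csv(rec, file.path(out, "specimens_season.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sp$bands, file.path(out, "season_bands.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$counts$breeding <- nrow(sp$breeding)
    manifest$counts$nonbreeding <- nrow(sp$nonbreeding)
    rec
  })

  # -- stage 3: climate ------------------------------------------------
  clim <- stage("climate", {
    rc <- record_climate(season, stk)
    diag <- climate_collinearity(rc$records)
    jsonlite::write_json(list(
      correlations = diag$correlations,
      vif_temp_precip = as.list(diag$vif_temp_precip),
      vif_ffd_precip = as.list(diag$vif_ffd_precip),
      chosen = diag$chosen
    ), file.path(out, "climate_diagnostics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
    pc <- proportional_change(stk, config$cutoff_year)
    for (v in names(pc$prop_change))
      write_ascii_grid(pc$prop_change[[v]], stk$grid,
                       file.path(out, sprintf("prop_change_%s.asc", v)))
    manifest$counts$zero_pre_cells <- sum(pc$n_zero_pre)
    list(records = rc$records, prop = pc, diag = diag)
  })

  # -- stage 4: historic spatial mixed models --------------------------
  historic <- stage("historic_lmm", {
    pre <- clim$records[clim$records$period == "pre", , drop = FALSE]
    res <- list()
    for (resp in config$responses_lmm) {
      dat <- if (resp == "julian_day")
        pre[pre$season == "breeding", , drop = FALSE] else pre
      fits <- fit_candidates(dat, resp, coords = config$lmm_coords,
                             scale_coords = config$scale_coords)
      sel <- select_and_average(fits, delta_max = config$delta_aicc)
      utils::write.csv(sel$table,
                       file.path(out, sprintf("model_table_%s.csv", resp)),
                       row.names = FALSE)
      utils::write.csv(sel$averaged,
                       file.path(out, sprintf("averaged_%s.csv", resp)),
                       row.names = FALSE)
      res[[resp]] <- sel
    }
    res
  })

  # -- stage 5: bootstrap trait maps + change --------------------------
  maps <- stage("maps", {
    res <- list()
    for (resp in config$responses_map) {
      per <- list()
      for (pd in c("pre", "post")) {
        dat <- season[season$period == pd, , drop = FALSE]
        if (resp == "julian_day")
          dat <- dat[dat$season == "breeding", , drop = FALSE]
        per[[pd]] <- bootstrap_maps(dat, resp, stk$grid, stk$dem, stk$mask,
                                    B = config$B,
                                    seed = config$seed +
                                      1000L * match(pd, c("pre", "post")))
      }
      cm <- change_map(per$pre, per$post)
      for (nm in c("delta", "delta_masked", "pooled_se"))
        write_ascii_grid(cm[[nm]], stk$grid,
                         file.path(out, sprintf("%s_%s.asc", nm, resp)))
      write_ascii_grid(cm$significant + 0, stk$grid,
                       file.path(out, sprintf("significant_%s.asc", resp)))
      jsonlite::write_json(
        list(r2_mean_pre = per$pre$r2_mean, mspe_pre = per$pre$mspe_mean,
             r2_mean_post = per$post$r2_mean, mspe_post = per$post$mspe_mean,
             redraws = per$pre$redraws + per$post$redraws,
             pct_significant =
               100 * mean(cm$significant[stk$mask], na.rm = TRUE)),
        file.path(out, sprintf("map_diagnostics_%s.json", resp)),
        auto_unbox = TRUE, digits = NA)
      res[[resp]] <- list(pre = per$pre, post = per$post, change = cm)
    }
    res
  })

  # -- stage 6: change GLS ---------------------------------------------
  gls <- stage("change_gls", {
    extras <- list(svl_female = maps$svl_female$change,
                   svl_male = maps$svl_male$change)
    pts <- sample_change_points(maps$julian_day$change, clim$prop,
                                n = config$n_points, seed = config$seed,
                                extra_deltas = extras)
    utils::write.csv(pts, file.path(out, "change_points.csv"),
                     row.names = FALSE)
    res <- list()
    specs <- list(julian_day = list(resp = "delta_trait", se = "pooled_se"),
                  svl_female = list(resp = "delta_svl_female",
                                    se = "se_svl_female"),
                  svl_male = list(resp = "delta_svl_male",
                                  se = "se_svl_male"))
    for (nm in names(specs)) {
      p2 <- pts
      p2$pooled_se <- pts[[specs[[nm]]$se]]
      p2$weight <- 1 / p2$pooled_se^2
      p2$weight <- p2$weight / mean(p2$weight)
      ea <- enumerate_and_average(p2, response = specs[[nm]]$resp,
                                  delta_max = config$delta_aicc,
                                  weight_mode = config$weight_mode)
      utils::write.csv(ea$selection$averaged,
                       file.path(out, sprintf("change_table_%s.csv", nm)),
                       row.names = FALSE)
      utils::write.csv(ea$selection$table,
                       file.path(out, sprintf("change_models_%s.csv", nm)),
                       row.names = FALSE)
      pe <- partial_effects(ea$selection, p2, axis = "F")
      utils::write.csv(pe, file.path(out,
                                     sprintf("partial_effects_%s.csv", nm)),
                       row.names = FALSE)
      res[[nm]] <- ea
    }
    res
  })

  # -- manifest --------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest$files <- stats::setNames(unname(sums),
                                    sub(paste0("^", out, "/?"), "", files))
  manifest$timings$total <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  manifest$version <- as.character(utils::packageVersion("traitshift"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(manifest,
              list(historic = historic, maps = maps, gls = gls,
                   collinearity = clim$diag)))
}
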