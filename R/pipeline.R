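#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline]. Either
#' `simulate` (parameters for [simulate_city]) or `inputs` (file paths for
#' deaths, census, projections, units, adjacency, ses) must be given.
#' Validation happens before any compute: an impossible MCMC schedule or a
#' missing input fails immediately.
#'
#' @param simulate named list of [simulate_city] arguments, or NULL.
#' @param inputs named list of file paths, or NULL.
#' @param open_age named open-ended ages per sex.
#' @param knots TOPALS knot ages.
#' @param mcmc list: iterations, burn_in, thin, sample_tau.
#' @param lambda_grid PCLM smoothing grid.
#' @param span LOESS span for the standard schedule.
#' @param seed integer seed for every stochastic stage.
#' @param sexes sexes to run.
#' @param index_ages LE index ages.
#' @param tau_spatial,tau_shape prior precisions of the spatial model.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            open_age = c(F = 103L, M = 100L),
                            knots = c(0, 1, 10, 20, 40, 70),
                            mcmc = list(iterations = 10000L,
                                        burn_in = 8000L, thin = 1L,
                                        sample_tau = FALSE),
                            lambda_grid = 10^seq(-2, 6, by = 1),
                            span = 0.3, seed = 1L,
                            sexes = c("F", "M"),
                            index_ages = c(0L, 20L, 40L, 60L),
                            tau_spatial = 5, tau_shape = 2) {
  cfg <- list(simulate = simulate, inputs = inputs, open_age = open_age,
              knots = knots, mcmc = utils::modifyList(
                list(iterations = 10000L, burn_in = 8000L, thin = 1L,
                     sample_tau = FALSE), mcmc),
              lambda_grid = lambda_grid, span = span,
              seed = as.integer(seed), sexes = sexes,
              index_ages = as.integer(index_ages),
              tau_spatial = tau_spatial, tau_shape = tau_shape)
  if (is.null(cfg$inputs) && is.null(cfg$simulate))
    stop("config needs either simulate parameters or input paths")
  m <- cfg$mcmc
  if (m$burn_in >= m$iterations)
    stop("burn_in must be smaller than iterations")
  if (m$thin < 1) stop("thin must be >= 1")
  if (!all(sexes %in% c("F", "M"))) stop("sexes must be F/M")
  if (!is.null(cfg$inputs)) {
    need <- c("deaths", "census", "projections", "units", "adjacency")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    absent <- !vapply(cfg$inputs[need], file.exists, logical(1))
    if (any(absent))
      stop("input file(s) not found: ",
           paste(unlist(cfg$inputs[need][absent]), collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$open_age)) y$open_age <- unlist(y$open_age)
  do.call(pipeline_config, y)
}

# stable content hash (polynomial rolling hash mod 2^31-1) for the manifest
config_hash <- function(cfg) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(cfg)),
                                      collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full small-area life-expectancy pipeline
#'
#' Chains the stages end to end: (optional) synthetic-city simulation, or
#' reading of real inputs; denominator estimation (census shares + PCLM
#' graduation + allocation + person-year exposure); standard-schedule
#' smoothing from the city totals; the spatial TOPALS fit per sex; life
#' tables for every retained draw; posterior LE summaries; and the inequity
#' statistics (gaps per sex and Rubin-pooled SIIs). Writes
#' `exposure.csv`, `standard_schedule.csv`, `le_summary.csv`, `gaps.csv`,
#' `sii.csv` and a `manifest.json` (seed, config, config hash, stage
#' timings, MCMC acceptance) into `out_dir`.
#'
#' @param config a [pipeline_config] (or list coerced through it).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`exposure`,
#'   `schedules`, `fits`, `le_draws`, `le_summary`, `gaps`, `sii`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 2)
    say(sprintf("[%s] %.1fs", stage, timings[[stage]]))
    r
  }

  if (!is.null(config$inputs)) {
    inp <- config$inputs
    deaths <- read_deaths(inp$deaths)
    census <- read_population(inp$census)
    projections <- read_projections(inp$projections)
    units <- read_units(inp$units)
    adjacency <- read_adjacency(inp$adjacency)
    ses <- if (!is.null(inp$ses)) read_ses(inp$ses)
    city <- NULL
  } else {
    city <- tick("simulate", do.call(simulate_city, utils::modifyList(
      list(seed = config$seed, open_age = config$open_age,
           knots = config$knots), config$simulate)))
    deaths <- city$deaths; census <- city$census
    projections <- city$projections; units <- city$units
    adjacency <- city$adjacency; ses <- city$ses
  }

  den <- tick("denominators", estimate_denominators(
    census, projections, units, open_age = config$open_age,
    lambda_grid = config$lambda_grid))
  write_population(den$exposure, file.path(out_dir, "exposure.csv"))

  fits <- list(); schedules <- list(); le_all <- NULL
  for (s in config$sexes) {
    Ds <- deaths[deaths$sex == s, ]
    Ns <- den$exposure[den$exposure$sex == s, ]
    by_age_d <- tapply(Ds$deaths, Ds$age, sum)
    by_age_n <- tapply(Ns$count, Ns$age, sum)
    all_ages <- as.integer(names(by_age_d))
    # fit on ages with exposure; extrapolate any empty open tail
    pos <- as.numeric(by_age_n) > 0
    schedules[[s]] <- tick(paste0("standard_", s), smooth_standard(
      as.numeric(by_age_d)[pos], as.numeric(by_age_n)[pos],
      span = config$span, ages = all_ages[pos], predict_ages = all_ages))
    model <- topals_model(Ds, Ns, schedules[[s]], adjacency,
                          knots = config$knots,
                          tau_spatial = config$tau_spatial,
                          tau_shape = config$tau_shape)
    fits[[s]] <- tick(paste0("fit_", s), run_mcmc(
      model, iterations = config$mcmc$iterations,
      burn_in = config$mcmc$burn_in, thin = config$mcmc$thin,
      seed = config$seed + match(s, c("F", "M")),
      sample_tau = isTRUE(config$mcmc$sample_tau)))
    le_all <- rbind(le_all, tick(paste0("lifetable_", s), le_draws(
      model, fits[[s]], index_ages = config$index_ages, sex = s)))
  }
  write_schedule(schedules, file.path(out_dir, "standard_schedule.csv"))

  le_summary <- summarize_draws(le_all)
  utils::write.csv(le_summary, file.path(out_dir, "le_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  gaps <- do.call(rbind, lapply(split(le_summary, le_summary[c("sex", "age")]),
                                function(d) {
    g <- gap_stats(d$le)
    data.frame(sex = d$sex[1], age = d$age[1],
               p90_p10 = g[["p90_p10"]], range = g[["range"]])
  }))
  rownames(gaps) <- NULL
  utils::write.csv(gaps, file.path(out_dir, "gaps.csv"), row.names = FALSE,
                   quote = FALSE)

  sii <- NULL
  if (!is.null(ses)) {
    sii <- tick("inequity", sii_analysis(le_all, ses))
    utils::write.csv(sii, file.path(out_dir, "sii.csv"), row.names = FALSE,
                     quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("saele")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(config),
    timings_sec = as.list(timings),
    acceptance = lapply(fits, function(f)
      round(unname(range(f$acceptance)), 3))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  invisible(list(city = city, exposure = den$exposure,
                 schedules = schedules, fits = fits, le_draws = le_all,
                 le_summary = le_summary, gaps = gaps, sii = sii,
                 manifest = manifest))
}
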