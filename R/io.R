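#' Readers and writers for the pipeline's CSV schemas
#'
#' The pipeline's interchange formats are plain CSVs with fixed headers:
#' deaths (`area,age,sex,deaths`), population/exposure (`area,age,sex,count`),
#' grouped projections (`unit,age_band,sex,period,count`), SES
#' (`area,` + variable columns), adjacency edge list (`area_i,area_j`),
#' units (`area,unit`) and standard schedules (`age,sex,log_rate`). Readers
#' validate the schema (error names the file and column), coerce types,
#' check that sexes are F/M and ages are nonnegative integers, and
#' symmetrize the adjacency. Writers emit exactly what the readers accept,
#' so every output round-trips.
#'
#' @param path file path.
#' @name saele-io
NULL

read_csv_checked <- function(path, required, integer_cols = character(),
                             numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read everything as character ("F" would otherwise parse as logical),
  # then coerce the declared numeric/integer columns
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  for (cc in integer_cols) {
    v <- suppressWarnings(as.integer(x[[cc]]))
    bad <- which(is.na(v) & !is.na(x[[cc]]))
    if (length(bad))
      stop(sprintf("%s: column %s row %d is not an integer", path, cc, bad[1]))
    x[[cc]] <- v
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v) & !is.na(x[[cc]]))
    if (length(bad))
      stop(sprintf("%s: column %s row %d is not numeric", path, cc, bad[1]))
    x[[cc]] <- v
  }
  x
}

check_sex_age <- function(x, path) {
  if (!all(x$sex %in% c("F", "M")))
    stop(path, ": sex must be coded F/M")
  if (any(x$age < 0)) stop(path, ": negative ages")
  invisible(x)
}

#' @rdname saele-io
#' @export
read_deaths <- function(path) {
  x <- read_csv_checked(path, c("area", "age", "sex", "deaths"),
                        integer_cols = c("age", "deaths"))
  check_sex_age(x, path)
  if (any(x$deaths < 0)) stop(path, ": negative death counts")
  x
}

#' @rdname saele-io
#' @export
read_population <- function(path) {
  x <- read_csv_checked(path, c("area", "age", "sex", "count"),
                        integer_cols = "age", numeric_cols = "count")
  check_sex_age(x, path)
  if (any(x$count < 0)) stop(path, ": negative counts")
  x
}

#' @rdname saele-io
#' @export
read_projections <- function(path) {
  x <- read_csv_checked(path, c("unit", "age_band", "sex", "period", "count"),
                        numeric_cols = "count")
  if (!all(x$sex %in% c("F", "M"))) stop(path, ": sex must be coded F/M")
  x$period <- as.character(x$period)
  x$band_lower <- as.integer(sub("[-+].*$", "", x$age_band))
  if (anyNA(x$band_lower)) stop(path, ": unparseable age_band labels")
  x
}

#' @rdname saele-io
#' @export
read_ses <- function(path) {
  x <- read_csv_checked(path, "area")
  if (ncol(x) < 2L) stop(path, ": no SES variable columns")
  x <- read_csv_checked(path, "area",
                        numeric_cols = setdiff(names(x), "area"))
  x
}

#' @rdname saele-io
#' @export
read_units <- function(path) {
  read_csv_checked(path, c("area", "unit"))
}

#' @rdname saele-io
#' @export
read_adjacency <- function(path) {
  x <- read_csv_checked(path, c("area_i", "area_j"))
  self <- x$area_i == x$area_j
  if (any(self)) {
    warning(path, ": dropping ", sum(self), " self-edge(s)")
    x <- x[!self, , drop = FALSE]
  }
  a <- pmin(x$area_i, x$area_j); b <- pmax(x$area_i, x$area_j)
  key <- paste(a, b)
  n_per_pair <- table(key)
  if (length(unique(n_per_pair)) > 1L)
    warning(path, ": mixed one-way and two-way edges; symmetrized")
  keep <- !duplicated(key)
  out <- data.frame(area_i = a[keep], area_j = b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname saele-io
#' @export
read_schedule <- function(path) {
  x <- read_csv_checked(path, c("age", "sex", "log_rate"),
                        integer_cols = "age", numeric_cols = "log_rate")
  lapply(split(x, x$sex), function(d) {
    d <- d[order(d$age), ]
    standard_schedule(d$age, d$log_rate)
  })
}

#' @rdname saele-io
#' @param x object to write (schema depends on the writer).
#' @export
write_deaths <- function(x, path) {
  utils::write.csv(x[c("area", "age", "sex", "deaths")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @export
write_population <- function(x, path) {
  utils::write.csv(x[c("area", "age", "sex", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @export
write_projections <- function(x, path) {
  utils::write.csv(x[c("unit", "age_band", "sex", "period", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @export
write_adjacency <- function(x, path) {
  utils::write.csv(x[c("area_i", "area_j")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @export
write_ses <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @export
write_units <- function(x, path) {
  utils::write.csv(x[c("area", "unit")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname saele-io
#' @param schedules named list of [standard_schedule] per sex.
#' @export
write_schedule <- function(schedules, path) {
  x <- do.call(rbind, lapply(names(schedules), function(s)
    data.frame(age = schedules[[s]]$age, sex = s,
               log_rate = schedules[[s]]$log_rate)))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic city's tables to a directory
#'
#' Emits deaths.csv, census.csv, projections.csv, ses.csv, adjacency.csv,
#' units.csv and the true standard schedules, in the schemas the readers
#' accept.
#'
#' @param city a [simulate_city] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_city <- function(city, dir) {
  stopifnot(inherits(city, "synthetic_city"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_deaths(city$deaths, file.path(dir, "deaths.csv"))
  write_population(city$census, file.path(dir, "census.csv"))
  write_projections(city$projections, file.path(dir, "projections.csv"))
  write_ses(city$ses, file.path(dir, "ses.csv"))
  write_adjacency(city$adjacency, file.path(dir, "adjacency.csv"))
  write_units(city$units, file.path(dir, "units.csv"))
  write_schedule(city$schedules, file.path(dir, "true_schedule.csv"))
  invisible(dir)
}

#' Read and reconcile all pipeline inputs
#'
#' Reads the input files, validates schemas, and reconciles area sets:
#' deaths registered in an area with no exposure are an error (the rate
#' would be undefined); areas present in exposure but absent from deaths
#' are kept with zero deaths and reported.
#'
#' @param deaths,exposure,adjacency,ses,units file paths (`ses`, `units`
#'   optional).
#' @return List of validated tables plus a `report` of reconciliation notes.
#' @export
read_inputs <- function(deaths, exposure, adjacency, ses = NULL,
                        units = NULL) {
  D <- read_deaths(deaths)
  N <- read_population(exposure)
  A <- read_adjacency(adjacency)
  report <- character(0)
  extra <- setdiff(unique(D$area), unique(N$area))
  if (length(extra))
    stop("deaths recorded for area(s) absent from exposure: ",
         paste(extra, collapse = ", "))
  silent <- setdiff(unique(N$area), unique(D$area))
  if (length(silent))
    report <- c(report, paste0("areas with exposure but no recorded deaths: ",
                               paste(silent, collapse = ", ")))
  out <- list(deaths = D, exposure = N, adjacency = A, report = report)
  if (!is.null(ses)) out$ses <- read_ses(ses)
  if (!is.null(units)) out$units <- read_units(units)
  out
}

#' Derive area adjacency from GeoJSON polygons
#'
#' Two areas are neighbors when their polygons share a full boundary
#' segment (a common edge between two consecutive vertices), not merely a
#' corner point. Segment matching is by canonicalized, coordinate-rounded
#' vertex pairs, which is exact for tilings whose polygons reuse the same
#' vertex chains (regular lattices, well-built census geographies); polygon
#' pairs that share a border drawn with non-matching vertices are not
#' detected.
#'
#' @param geojson path to a GeoJSON FeatureCollection, or the parsed list.
#' @param id_property feature property holding the area identifier.
#' @param digits coordinate rounding used for vertex matching.
#' @return Data frame of undirected edges `area_i, area_j`; warns when the
#'   resulting graph leaves some areas with no neighbors.
#' @export
derive_adjacency <- function(geojson, id_property = "area", digits = 9) {
  g <- if (is.character(geojson)) {
    jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  } else geojson
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  seg_tab <- new.env(parent = emptyenv())
  ids <- character(length(g$features))
  for (fi in seq_along(g$features)) {
    f <- g$features[[fi]]
    id <- f$properties[[id_property]]
    if (is.null(id)) id <- if (!is.null(f$id)) f$id else as.character(fi)
    ids[fi] <- as.character(id)
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon"))
      stop("feature ", ids[fi], ": invalid or unsupported geometry")
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else
      geom$coordinates
    for (poly in polys) for (ring in poly) {
      pts <- vapply(ring, function(p)
        paste(round(as.numeric(p[[1]]), digits),
              round(as.numeric(p[[2]]), digits)), character(1))
      if (length(pts) < 4L) stop("feature ", ids[fi], ": degenerate ring")
      for (k in seq_len(length(pts) - 1L)) {
        seg <- paste(sort(c(pts[k], pts[k + 1L])), collapse = "|")
        seg_tab[[seg]] <- c(seg_tab[[seg]], fi)
      }
    }
  }
  pairs <- unique(do.call(rbind, lapply(ls(seg_tab), function(s) {
    f <- unique(seg_tab[[s]])
    if (length(f) < 2L) return(NULL)
    t(utils::combn(sort(f), 2L))
  })))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no shared boundary segments: areas are disjoint")
    return(data.frame(area_i = character(0), area_j = character(0)))
  }
  out <- data.frame(area_i = ids[pairs[, 1]], area_j = ids[pairs[, 2]],
                    stringsAsFactors = FALSE)
  isolated <- setdiff(ids, c(out$area_i, out$area_j))
  if (length(isolated))
    warning("area(s) with no neighbors: ", paste(isolated, collapse = ", "))
  out[order(out$area_i, out$area_j), , drop = FALSE]
}

#' Export a life-expectancy choropleth as GeoJSON
#'
#' Attaches LE summary columns as feature properties on the input polygons
#' (no styling); a minimal mapping export.
#'
#' @param geojson path to polygons or parsed FeatureCollection.
#' @param le_summary data frame from [summarize_draws] for a single sex and
#'   index age.
#' @param path output file.
#' @param id_property feature property holding the area identifier.
#' @export
write_choropleth <- function(geojson, le_summary, path,
                             id_property = "area") {
  g <- if (is.character(geojson)) {
    jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  } else geojson
  for (fi in seq_along(g$features)) {
    id <- g$features[[fi]]$properties[[id_property]]
    i <- match(as.character(id), as.character(le_summary$area))
    if (!is.na(i)) {
      g$features[[fi]]$properties$le <- le_summary$le[i]
      g$features[[fi]]$properties$le_lower <- le_summary$le_lower[i]
      g$features[[fi]]$properties$le_upper <- le_summary$le_upper[i]
    }
  }
  jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
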