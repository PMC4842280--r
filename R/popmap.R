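#' Sample-to-population map with site coordinates
#'
#' Associates every sample with a population, and (optionally) every
#' population with geographic coordinates and a region label. Coordinates
#' drive the spatial analyses (great-circle distances, landscape surface).
#'
#' @param sample_to_pop named character vector: names = sample ids,
#'   values = population ids.
#' @param pop_coords optional data.frame with columns `population`,
#'   `latitude`, `longitude` (decimal degrees).
#' @param pop_region optional named character vector: population -> region.
#' @return An object of class `population_set`.
#' @export
population_set <- function(sample_to_pop, pop_coords = NULL, pop_region = NULL) {
  if (is.null(names(sample_to_pop)) || any(!nzchar(names(sample_to_pop)))) {
    stop("population_set: sample_to_pop must be a named vector", call. = FALSE)
  }
  if (anyDuplicated(names(sample_to_pop))) {
    stop("population_set: duplicate sample ids", call. = FALSE)
  }
  if (!is.null(pop_coords)) {
    need <- c("population", "latitude", "longitude")
    if (!all(need %in% names(pop_coords))) {
      stop("population_set: pop_coords needs columns population, latitude, longitude",
           call. = FALSE)
    }
    if (any(abs(pop_coords$latitude) > 90)) {
      stop("range error: latitude outside [-90, 90]", call. = FALSE)
    }
    if (any(abs(pop_coords$longitude) > 180)) {
      stop("range error: longitude outside [-180, 180]", call. = FALSE)
    }
    rownames(pop_coords) <- pop_coords$population
  }
  structure(list(sample_to_pop = sample_to_pop,
                 pop_coords = pop_coords,
                 pop_region = pop_region),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat(sprintf("<population_set> %d samples, %d populations%s\n",
              length(x$sample_to_pop), length(unique(x$sample_to_pop)),
              if (is.null(x$pop_coords)) "" else " (with coordinates)"))
  invisible(x)
}

#' Population ids of a population set
#' @param pops a [population_set()].
#' @return character vector of population ids, in order of first appearance.
#' @export
populations <- function(pops) unique(unname(pops$sample_to_pop))

#' Parse degree-minute coordinate strings to decimal degrees
#'
#' Collection-site tables commonly give latitude/longitude as degree-minute
#' strings such as `24°51'`; decimal degrees = degrees + minutes/60.
#' Plain numeric strings pass through unchanged.
#'
#' @param x character (or numeric) vector of coordinates.
#' @return numeric vector of decimal degrees.
#' @export
parse_dms <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  idx <- which(is.na(out) & nzchar(x))
  for (i in idx) {
    m <- regmatches(x[i], regexec("^([0-9]+(?:\\.[0-9]+)?)[^0-9]+([0-9]+(?:\\.[0-9]+)?)", x[i]))[[1L]]
    if (length(m) == 3L) {
      out[i] <- as.numeric(m[2L]) + as.numeric(m[3L]) / 60
    } else {
      stop(sprintf("cannot parse coordinate '%s'", x[i]), call. = FALSE)
    }
  }
  out
}

#' Read a population map TSV
#'
#' Expected columns: `sample`, `population`, and optionally `latitude`,
#' `longitude` (decimal degrees or degree-minute strings) and `region`.
#' Coordinates must be consistent within a population.
#'
#' @param path TSV path.
#' @return a [population_set()].
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  known <- c("sample", "population", "latitude", "longitude", "region")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    stop(sprintf("schema error: unknown column(s) %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(c("sample", "population") %in% names(df))) {
    stop("schema error: columns 'sample' and 'population' are required", call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop(sprintf("schema error: duplicate sample id '%s'",
                 df$sample[anyDuplicated(df$sample)][1L]), call. = FALSE)
  }
  s2p <- stats::setNames(df$population, df$sample)
  coords <- NULL
  if (all(c("latitude", "longitude") %in% names(df))) {
    lat <- parse_dms(df$latitude)
    lon <- parse_dms(df$longitude)
    keep <- !is.na(lat) & !is.na(lon)
    if (any(keep)) {
      cc <- unique(data.frame(population = df$population[keep],
                              latitude = lat[keep], longitude = lon[keep],
                              stringsAsFactors = FALSE))
      if (anyDuplicated(cc$population)) {
        stop("schema error: inconsistent coordinates within a population", call. = FALSE)
      }
      coords <- cc
    }
  }
  region <- NULL
  if ("region" %in% names(df)) {
    rr <- unique(df[, c("population", "region")])
    if (anyDuplicated(rr$population)) {
      stop("schema error: inconsistent region within a population", call. = FALSE)
    }
    region <- stats::setNames(rr$region, rr$population)
  }
  population_set(s2p, coords, region)
}

#' Write a population map TSV
#' @param pops a [population_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pops, path) {
  df <- data.frame(sample = names(pops$sample_to_pop),
                   population = unname(pops$sample_to_pop),
                   stringsAsFactors = FALSE)
  if (!is.null(pops$pop_coords)) {
    df$latitude <- pops$pop_coords[df$population, "latitude"]
    df$longitude <- pops$pop_coords[df$population, "longitude"]
  }
  if (!is.null(pops$pop_region)) df$region <- unname(pops$pop_region[df$population])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
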