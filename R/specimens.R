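#' Read and validate a specimen table
#'
#' Reads a delimited text file (CSV or TSV) of georeferenced specimen records,
#' one row per collected individual, and validates coordinates, elevations and
#' species-hypothesis labels. The result is the substrate of every downstream
#' analysis: incidence matrices, richness estimation, similarity, beta
#' diversity, ecotone detection and delimitation comparison.
#'
#' Canonical columns are \code{specimen_id}, \code{path}, \code{locality},
#' \code{latitude}, \code{longitude}, \code{elevation_m}, one or more
#' \code{species_<hypothesis>} columns, and optional \code{haplotype} and
#' \code{visit_date}. Non-canonical column names can be mapped via
#' \code{schema}.
#'
#' @param source path to a delimited text file, or a connection.
#' @param schema named character vector mapping canonical column names to the
#'   file's column names, e.g. \code{c(elevation_m = "elev")}. Columns already
#'   canonically named need not be listed.
#' @param delim field delimiter; \code{NULL} (default) auto-detects comma vs
#'   tab from the header line.
#' @return An object of class \code{specimen_table}: a \code{data.frame} of
#'   validated records with attributes \code{hypotheses} (character vector of
#'   species-hypothesis names) and \code{n_dropped} (rows removed by
#'   validation, reported with row numbers via a warning).
#' @export
read_specimen_table <- function(source, schema = NULL, delim = NULL) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("input file not found: ", source)
    header <- readLines(source, n = 1L)
    if (length(header) == 0L || !nzchar(header)) stop("empty input file")
    if (is.null(delim)) {
      delim <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0)
        "\t" else ","
    }
    df <- utils::read.table(source, header = TRUE, sep = delim,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
  } else {
    df <- utils::read.table(source, header = TRUE,
                            sep = if (is.null(delim)) "," else delim,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(df) == 0L) stop("empty input: no specimen rows")

  # apply schema renames (canonical = file column)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(df))
      if (is.na(j)) stop("schema error: column '", schema[[canon]],
                         "' (for '", canon, "') not found")
      names(df)[j] <- canon
    }
  }
  required <- c("specimen_id", "path", "locality", "latitude", "longitude",
                "elevation_m")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  hyp_cols <- grep("^species_", names(df), value = TRUE)
  if (length(hyp_cols) == 0L)
    stop("schema error: at least one species_<hypothesis> column required")

  for (col in c("latitude", "longitude", "elevation_m"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  ok <- !is.na(df$latitude) & df$latitude >= -90 & df$latitude <= 90 &
    !is.na(df$longitude) & df$longitude >= -180 & df$longitude <= 180 &
    !is.na(df$elevation_m) & df$elevation_m >= 0
  # at least one non-missing species label
  has_label <- Reduce(`|`, lapply(hyp_cols, function(h) {
    v <- df[[h]]
    !is.na(v) & nzchar(trimws(as.character(v)))
  }))
  ok <- ok & has_label
  if (any(!ok))
    warning(sum(!ok), " row(s) failed validation and were dropped (rows: ",
            paste(utils::head(which(!ok), 20), collapse = ", "), ")")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid specimen rows after validation")
  if (anyDuplicated(df$specimen_id))
    stop("specimen_id values are not unique")

  new_specimen_table(df, n_dropped = sum(!ok))
}

new_specimen_table <- function(df, n_dropped = 0L) {
  hyp_cols <- grep("^species_", names(df), value = TRUE)
  structure(df,
            hypotheses = sub("^species_", "", hyp_cols),
            n_dropped = as.integer(n_dropped),
            class = c("specimen_table", "data.frame"))
}

#' @export
print.specimen_table <- function(x, ...) {
  cat("<specimen_table> ", nrow(x), " specimens, ",
      length(unique(x$locality)), " localities, hypotheses: ",
      paste(attr(x, "hypotheses"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Species hypotheses available in a specimen table
#' @param table a \code{specimen_table}.
#' @return Character vector of hypothesis names.
#' @export
hypotheses <- function(table) attr(table, "hypotheses")

species_column <- function(table, hypothesis) {
  col <- paste0("species_", hypothesis)
  if (!col %in% names(table))
    stop("unknown species hypothesis: '", hypothesis, "'")
  v <- as.character(table[[col]])
  v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
  v
}

#' Build a species-by-unit incidence matrix
#'
#' Collapses specimen records to presence/absence of each species across
#' sample-units. The unit is configurable: the georeferenced locality point
#' (default), the forest path, fixed-width elevation bins, a biome compartment
#' at an elevation threshold, or any custom record-to-unit assignment.
#'
#' @param table a \code{specimen_table}.
#' @param hypothesis which species-hypothesis column to use.
#' @param unit one of \code{"locality"}, \code{"path"},
#'   \code{"elevation_bin"}, \code{"biome"}, or a vector of unit labels with
#'   one element per record (custom map; \code{NA} drops the record).
#' @param bin_width elevation bin width in metres (for
#'   \code{unit = "elevation_bin"}).
#' @param threshold_m biome boundary in metres (for \code{unit = "biome"}).
#' @return An \code{incidence_matrix}: integer 0/1 matrix, species as rows and
#'   sample-units as columns, with attributes \code{unit_definition} and
#'   \code{n_dropped} (records without a resolvable unit or species label).
#' @export
build_incidence <- function(table, hypothesis, unit = "locality",
                            bin_width = 40, threshold_m = 300) {
  sp <- species_column(table, hypothesis)
  if (is.character(unit) && length(unit) == 1L) {
    units <- switch(unit,
      locality = as.character(table$locality),
      path = as.character(table$path),
      elevation_bin = {
        k <- floor(table$elevation_m / bin_width)
        sprintf("[%g,%g)", k * bin_width, (k + 1) * bin_width)
      },
      biome = assign_biome(table, threshold_m)$labels,
      stop("unknown unit definition: ", unit))
    unit_def <- unit
  } else {
    if (length(unit) != nrow(table))
      stop("custom unit map must have one element per record")
    units <- as.character(unit)
    unit_def <- "custom"
  }
  keep <- !is.na(sp) & !is.na(units)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " record(s) without species label or unit dropped")
  if (!any(keep)) stop("zero resolvable records")
  sp <- sp[keep]; units <- units[keep]
  species <- sort(unique(sp))
  unit_lev <- sort(unique(units))
  X <- matrix(0L, length(species), length(unit_lev),
              dimnames = list(species, unit_lev))
  X[cbind(match(sp, species), match(units, unit_lev))] <- 1L
  structure(X, unit_definition = unit_def, n_dropped = n_drop,
            class = c("incidence_matrix", class(X)))
}

#' Assign records to biomes by an elevation threshold
#'
#' Labels every record \code{"dry"} or \code{"moist"} by the half-open
#' convention: elevation in \code{[0, t)} is dry, \code{[t, Inf)} is moist.
#'
#' @param table a \code{specimen_table} (or any data.frame with
#'   \code{elevation_m}).
#' @param threshold_m boundary elevation in metres; must be positive.
#' @return A list with \code{threshold} and \code{labels} (character vector,
#'   one per record).
#' @export
assign_biome <- function(table, threshold_m = 300) {
  if (!is.numeric(threshold_m) || length(threshold_m) != 1L ||
      is.na(threshold_m) || threshold_m <= 0)
    stop("threshold_m must be a single positive number")
  labels <- ifelse(table$elevation_m < threshold_m, "dry", "moist")
  list(threshold = threshold_m, labels = labels)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitude out of range [-180, 180]")
  R <- 6371.0088
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Maximum pairwise distance between locality points
#'
#' Scans all pairs of distinct locality points and returns the farthest pair.
#' Ties are broken by lexicographic order of the locality-code pair.
#'
#' @param table a \code{specimen_table} or a locality data.frame with columns
#'   \code{locality}, \code{latitude}, \code{longitude} (and \code{path} if
#'   \code{exclude_paths} is used).
#' @param exclude_paths character vector of path codes to drop before the scan
#'   (e.g. \code{"DH"}, the outlying path).
#' @return List with \code{locality1}, \code{locality2}, \code{km}.
#' @export
max_pairwise_distance <- function(table, exclude_paths = character()) {
  df <- as.data.frame(table)
  if (length(exclude_paths) && "path" %in% names(df))
    df <- df[!df$path %in% exclude_paths, , drop = FALSE]
  pts <- unique(df[, c("locality", "latitude", "longitude")])
  pts <- pts[order(pts$locality), , drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 distinct localities")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- great_circle_km(pts$latitude[ij[, 1]], pts$longitude[ij[, 1]],
                       pts$latitude[ij[, 2]], pts$longitude[ij[, 2]])
  best <- which(d == max(d))
  # deterministic tie-break: lexicographic (locality1, locality2)
  if (length(best) > 1L) {
    key <- paste(pts$locality[ij[best, 1]], pts$locality[ij[best, 2]])
    best <- best[order(key)][1L]
  }
  list(locality1 = pts$locality[ij[best, 1]],
       locality2 = pts$locality[ij[best, 2]],
       km = d[best])
}

#' Count singleton species
#'
#' A singleton is a species represented by exactly one individual (or, with
#' \code{basis = "haplotypes"}, exactly one haplotype) in the whole table.
#'
#' @param table a \code{specimen_table}.
#' @param hypothesis species-hypothesis name.
#' @param basis \code{"individuals"} (default) or \code{"haplotypes"}.
#' @return List with \code{count} and \code{fraction} (of observed species).
#' @export
summarize_singletons <- function(table, hypothesis,
                                 basis = c("individuals", "haplotypes")) {
  basis <- match.arg(basis)
  sp <- species_column(table, hypothesis)
  keep <- !is.na(sp)
  sp <- sp[keep]
  if (basis == "haplotypes") {
    if (!"haplotype" %in% names(table) || all(is.na(table$haplotype)))
      stop("basis = 'haplotypes' requires a haplotype column")
    hap <- as.character(table$haplotype)[keep]
    n_per_sp <- tapply(hap, sp, function(h) length(unique(h)))
  } else {
    n_per_sp <- table(sp)
  }
  s_obs <- length(n_per_sp)
  count <- sum(n_per_sp == 1L)
  list(count = as.integer(count),
       fraction = if (s_obs > 0) count / s_obs else 0)
}

#' Reference locality layout of the Nui Chua National Park survey
#'
#' The 65 georeferenced locality points (with elevations and specimen counts)
#' of a published leaf-beetle survey along six forest paths radiating from
#' Vinh Hy in the Nui Chua National Park, South Vietnam. Locality codes
#' DD1'-DD5' of the original table are stored as DD1b-DD5b.
#'
#' @param exclude_dh drop the outlying Da Hang (DH) path, which the survey
#'   discarded for community analyses (default TRUE; 60 points remain).
#' @return data.frame with columns \code{path}, \code{locality},
#'   \code{latitude}, \code{longitude}, \code{elevation_m},
#'   \code{n_specimens}.
#' @export
nui_chua_localities <- function(exclude_dh = TRUE) {
  f <- system.file("extdata", "nui_chua_localities.csv", package = "betagrad",
                   mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  if (exclude_dh) df <- df[df$path != "DH", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an incidence matrix as TSV with a JSON metadata sidecar
#'
#' @param X an \code{incidence_matrix}.
#' @param file output TSV path; \code{<file>.json} receives the metadata.
#' @return \code{file}, invisibly.
#' @export
write_incidence <- function(X, file) {
  df <- data.frame(species = rownames(X), as.data.frame(unclass(X)),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(unit_definition = attr(X, "unit_definition"),
               n_species = nrow(X), n_units = ncol(X),
               n_dropped = attr(X, "n_dropped"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}
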