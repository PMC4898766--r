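#' Configure a synthetic gradient community
#'
#' Describes a two-pool community on an elevation gradient: a species pool
#' adapted to drier, lower elevations and one adapted to moister, higher
#' elevations, overlapping in an ecotone band. Specimens are generated by a
#' per-visit Bernoulli detection model with species-specific log-normal
#' abundance multipliers; the baseline detection rate can be calibrated so the
#' expected fraction of singleton species (species observed as exactly one
#' individual) matches a target.
#'
#' @param localities data.frame with columns \code{path}, \code{locality},
#'   \code{latitude}, \code{longitude}, \code{elevation_m}.
#' @param n_species_dry,n_species_moist pool sizes.
#' @param center_dry,center_moist \code{c(mean, sd)} in metres of elevational
#'   range centres per pool.
#' @param width \code{c(mean, sd)} in metres of elevational range widths.
#' @param min_width ranges narrower than this are widened to it (metres).
#' @param ecotone_band \code{c(low, high)} metres: the stated overlap band.
#' @param true_boundary metres; must lie inside \code{ecotone_band}.
#' @param visits named integer vector of visits per path (names = path codes),
#'   or a single integer applied to every path.
#' @param baseline_detection per-species per-visit occurrence probability
#'   before the abundance multiplier; \code{NULL} (default) calibrates it to
#'   \code{target_singleton_fraction}.
#' @param abundance_sdlog sd of the log-normal abundance multiplier
#'   (mean-1 parameterisation).
#' @param target_singleton_fraction desired expected proportion of observed
#'   species that are singletons; used only when \code{baseline_detection} is
#'   \code{NULL}.
#' @param range_shape \code{"rectangular"} (hard range limits, default) or
#'   \code{"gaussian"} (occupancy decays smoothly away from the centre).
#' @param seed integer seed; the same config and seed reproduce identical
#'   output.
#' @return A \code{gradient_config} list.
#' @export
gradient_config <- function(localities,
                            n_species_dry = 80, n_species_moist = 75,
                            center_dry = c(170, 60),
                            center_moist = c(430, 60),
                            width = c(260, 60), min_width = 40,
                            ecotone_band = c(160, 320),
                            true_boundary = 300,
                            visits = 8L,
                            baseline_detection = NULL,
                            abundance_sdlog = 1.2,
                            target_singleton_fraction = 0.497,
                            range_shape = c("rectangular", "gaussian"),
                            seed = 1L) {
  range_shape <- match.arg(range_shape)
  stopifnot(n_species_dry > 0, n_species_moist > 0,
            length(ecotone_band) == 2L, min_width > 0,
            abundance_sdlog >= 0)
  if (ecotone_band[1] >= ecotone_band[2])
    stop("ecotone_band low must be < high")
  if (true_boundary <= ecotone_band[1] || true_boundary > ecotone_band[2])
    stop("true_boundary must lie inside ecotone_band")
  if (!is.null(baseline_detection) &&
      (baseline_detection <= 0 || baseline_detection > 1))
    stop("baseline_detection must be in (0, 1]")
  if (!is.null(target_singleton_fraction) &&
      (target_singleton_fraction < 0 || target_singleton_fraction > 1))
    stop("target_singleton_fraction must be in [0, 1]")
  need <- c("path", "locality", "latitude", "longitude", "elevation_m")
  if (!all(need %in% names(localities)))
    stop("localities must have columns: ", paste(need, collapse = ", "))
  span <- range(localities$elevation_m)
  if (ecotone_band[2] <= span[1] || ecotone_band[1] >= span[2])
    stop("config error: ecotone_band lies outside the elevation span ",
         "of the localities")
  if (length(visits) == 1L && is.null(names(visits)))
    visits <- stats::setNames(rep(as.integer(visits),
                                  length(unique(localities$path))),
                              unique(localities$path))
  miss <- setdiff(unique(localities$path), names(visits))
  if (length(miss)) stop("visits missing for path(s): ",
                         paste(miss, collapse = ", "))
  if (any(visits < 1)) stop("visits must be positive")
  structure(list(localities = localities,
                 n_species_dry = n_species_dry,
                 n_species_moist = n_species_moist,
                 center_dry = center_dry, center_moist = center_moist,
                 width = width, min_width = min_width,
                 ecotone_band = ecotone_band, true_boundary = true_boundary,
                 visits = visits,
                 baseline_detection = baseline_detection,
                 abundance_sdlog = abundance_sdlog,
                 target_singleton_fraction = target_singleton_fraction,
                 range_shape = range_shape, seed = as.integer(seed)),
            class = "gradient_config")
}

#' Default configuration emulating the Nui Chua survey
#'
#' Sixty locality points of the Nui Chua reference layout (Da Hang excluded),
#' 155 species split 80 dry / 75 moist, ecotone band 160-320 m with true
#' boundary 300 m, four visits on the two low paths (AH, DD) and ten on the
#' three high ones (MN, NO, ST), and a singleton-fraction target of 0.497.
#'
#' @param seed integer seed.
#' @return A \code{gradient_config}.
#' @export
nui_chua_default_config <- function(seed = 1L) {
  gradient_config(localities = nui_chua_localities(exclude_dh = TRUE),
                  visits = c(AH = 4L, DD = 4L, MN = 10L, NO = 10L, ST = 10L),
                  seed = seed)
}

#' Generate a synthetic specimen table with ground truth
#'
#' Draws species elevational ranges from the configured pools, calibrates the
#' baseline detection rate to the singleton-fraction target (if requested),
#' and emits one specimen per successful per-visit Bernoulli detection.
#' Draw order is canonical (species-major, locality-minor, visit-innermost),
#' so a given config and seed reproduce identical tables.
#'
#' @param config a \code{gradient_config}.
#' @return List with \code{table} (a \code{specimen_table}) and \code{truth}
#'   (list: per-species data.frame \code{species} with pool, range and
#'   detection parameters; \code{true_boundary}; \code{ecotone_band};
#'   \code{baseline_detection} actually used).
#' @export
generate_gradient_community <- function(config) {
  stopifnot(inherits(config, "gradient_config"))
  set.seed(config$seed)
  loc <- config$localities
  n_loc <- nrow(loc)
  visits <- config$visits[as.character(loc$path)]

  n_dry <- config$n_species_dry
  n_moist <- config$n_species_moist
  S <- n_dry + n_moist
  pool <- rep(c("dry", "moist"), c(n_dry, n_moist))
  sp_id <- sprintf("sp%03d", seq_len(S))
  center <- c(stats::rnorm(n_dry, config$center_dry[1], config$center_dry[2]),
              stats::rnorm(n_moist, config$center_moist[1],
                           config$center_moist[2]))
  wid <- pmax(config$min_width,
              stats::rnorm(S, config$width[1], config$width[2]))
  lo <- center - wid / 2
  hi <- center + wid / 2
  sdlog <- config$abundance_sdlog
  mult <- if (sdlog > 0)
    stats::rlnorm(S, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, S)

  # per-species per-locality occupancy weight
  occ <- matrix(0, S, n_loc)
  for (s in seq_len(S)) {
    if (config$range_shape == "rectangular") {
      occ[s, ] <- as.numeric(loc$elevation_m >= lo[s] &
                               loc$elevation_m < hi[s])
    } else {
      occ[s, ] <- exp(-(loc$elevation_m - center[s])^2 / (2 * (wid[s] / 4)^2))
    }
  }

  baseline <- config$baseline_detection
  if (is.null(baseline)) {
    target <- config$target_singleton_fraction
    if (is.null(target))
      stop("either baseline_detection or target_singleton_fraction required")
    baseline <- calibrate_baseline(occ, visits, mult, target)
  }

  rows <- vector("list", S)
  n_emitted <- 0L
  for (s in seq_len(S)) {   # canonical order: species-major
    j <- which(occ[s, ] > 0)
    if (!length(j)) next
    p <- pmin(1, baseline * mult[s] * occ[s, j])
    reps <- visits[j]
    # locality-minor, visit-innermost
    det <- stats::rbinom(sum(reps), 1L, rep(p, reps))
    if (!any(det == 1L)) next
    loc_idx <- rep(j, reps)[det == 1L]
    visit_no <- unlist(lapply(reps, seq_len), use.names = FALSE)[det == 1L]
    rows[[s]] <- data.frame(loc_idx = loc_idx, visit = visit_no,
                            species = sp_id[s], stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no specimens generated; detection model too weak")
  n <- nrow(rows)
  tab <- data.frame(
    specimen_id = sprintf("S%05d", seq_len(n)),
    path = loc$path[rows$loc_idx],
    locality = loc$locality[rows$loc_idx],
    latitude = loc$latitude[rows$loc_idx],
    longitude = loc$longitude[rows$loc_idx],
    elevation_m = loc$elevation_m[rows$loc_idx],
    species_true = rows$species,
    haplotype = sprintf("H%05d", seq_len(n)),
    visit_date = as.character(as.Date("2012-06-01") + 30L * (rows$visit - 1L)),
    stringsAsFactors = FALSE)
  truth <- list(
    species = data.frame(species = sp_id, pool = pool, range_center = center,
                         range_width = wid, range_low = lo, range_high = hi,
                         abundance_multiplier = mult,
                         stringsAsFactors = FALSE),
    true_boundary = config$true_boundary,
    ecotone_band = config$ecotone_band,
    baseline_detection = baseline)
  list(table = new_specimen_table(tab), truth = truth)
}

# Expected singleton fraction of the detection model, given occupancy weights,
# visits per locality and abundance multipliers; solve for the baseline rate.
expected_singleton_fraction <- function(baseline, occ, visits, mult) {
  S <- nrow(occ)
  p_one <- p_obs <- numeric(S)
  for (s in seq_len(S)) {
    j <- which(occ[s, ] > 0)
    if (!length(j)) next
    p <- pmin(1, baseline * mult[s] * occ[s, j])
    trials <- rep(p, visits[j])
    q <- 1 - trials
    all_zero <- prod(q)
    # P(exactly one detection) across independent non-identical Bernoullis
    p_one[s] <- if (all_zero > 0) all_zero * sum(trials / q) else
      sum(trials * vapply(seq_along(trials),
                          function(k) prod(q[-k]), numeric(1)))
    p_obs[s] <- 1 - all_zero
  }
  if (sum(p_obs) == 0) return(NA_real_)
  sum(p_one) / sum(p_obs)
}

calibrate_baseline <- function(occ, visits, mult, target) {
  f <- function(lb) {
    expected_singleton_fraction(10^lb, occ, visits, mult) - target
  }
  lo <- -5; hi <- 0
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("cannot calibrate baseline detection to singleton target ", target)
  10^stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}
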