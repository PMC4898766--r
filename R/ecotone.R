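#' Slice specimens into fixed-width elevation bins
#'
#' Bins are half-open intervals \code{[k*w, (k+1)*w)} anchored at 0 m a.s.l.
#' and cover the data's elevation span contiguously; intermediate bins with
#' no records are retained as empty.
#'
#' @param table a \code{specimen_table}.
#' @param width bin width in metres (default 40, matching the sliding-window
#'   analysis the package implements).
#' @return List of class \code{elevation_bins}: \code{width}, \code{breaks}
#'   (bin edges), \code{bins} (data.frame \code{low}, \code{high},
#'   \code{n_records}), \code{bin_index} (per record), and the source table.
#' @export
slice_elevation <- function(table, width = 40) {
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  elev <- table$elevation_m
  if (!length(elev)) stop("no records with elevations")
  k <- floor(elev / width)
  kr <- seq(min(k), max(k))
  bins <- data.frame(low = kr * width, high = (kr + 1) * width,
                     n_records = as.integer(tabulate(k - min(k) + 1L,
                                                     nbins = length(kr))))
  structure(list(width = width, breaks = c(bins$low, bins$high[nrow(bins)]),
                 bins = bins, bin_index = k - min(k) + 1L, table = table),
            class = "elevation_bins")
}

#' Sliding-window profile of adjacent-bin composition
#'
#' For each pair of adjacent elevation bins sharing edge t, computes the
#' Sorensen-Dice similarity of the two bins' species sets, plus species
#' exclusivity counts around t. In \code{"global"} mode, exclusivity counts
#' species whose every record in the whole table lies below (or at/above) t;
#' in \code{"pairwise"} mode it counts species present only in the lower (or
#' only in the upper) bin of the pair. Optionally species represented by a
#' single individual in the full table (singletons) are removed before all
#' computations.
#'
#' @param bins an \code{elevation_bins}.
#' @param hypothesis species-hypothesis name.
#' @param exclude_singletons drop singleton species first (default FALSE).
#' @param exclusivity_mode \code{"global"} (default) or \code{"pairwise"}.
#' @return data.frame of class \code{sliding_profile}, one row per comparison:
#'   \code{boundary_elev}, \code{shared_index}, \code{below_exclusive},
#'   \code{above_exclusive}; attributes record width, mode and singleton
#'   policy.
#' @export
sliding_profile <- function(bins, hypothesis, exclude_singletons = FALSE,
                            exclusivity_mode = c("global", "pairwise")) {
  exclusivity_mode <- match.arg(exclusivity_mode)
  stopifnot(inherits(bins, "elevation_bins"))
  tab <- bins$table
  sp <- species_column(tab, hypothesis)
  keep <- !is.na(sp)
  sp <- sp[keep]
  bi <- bins$bin_index[keep]
  elev <- tab$elevation_m[keep]
  if (exclude_singletons) {
    n_per <- table(sp)
    drop <- names(n_per)[n_per == 1L]
    keep2 <- !(sp %in% drop)
    sp <- sp[keep2]; bi <- bi[keep2]; elev <- elev[keep2]
  }
  if (!length(sp)) stop("no records left after filtering")
  sets <- split(sp, factor(bi, levels = seq_len(nrow(bins$bins))))
  sets <- lapply(sets, unique)
  nonempty <- which(vapply(sets, length, 0L) > 0)
  if (length(nonempty) < 2L) stop("fewer than 2 non-empty elevation bins")
  out <- list()
  for (i in seq_len(nrow(bins$bins) - 1L)) {
    lower <- sets[[i]]; upper <- sets[[i + 1L]]
    if (!length(lower) && !length(upper)) next
    t_edge <- bins$bins$high[i]
    shared <- if (length(lower) || length(upper)) {
      a <- length(intersect(lower, upper))
      2 * a / (2 * a + length(setdiff(lower, upper)) +
                 length(setdiff(upper, lower)))
    } else NA_real_
    if (exclusivity_mode == "global") {
      below <- sum(tapply(elev, sp, max) < t_edge)
      above <- sum(tapply(elev, sp, min) >= t_edge)
    } else {
      below <- length(setdiff(lower, upper))
      above <- length(setdiff(upper, lower))
    }
    out[[length(out) + 1L]] <-
      data.frame(boundary_elev = t_edge, shared_index = shared,
                 below_exclusive = as.integer(below),
                 above_exclusive = as.integer(above))
  }
  prof <- do.call(rbind, out)
  prof <- prof[order(prof$boundary_elev), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, width = bins$width, exclusivity_mode = exclusivity_mode,
            singleton_policy = if (exclude_singletons) "excluded" else
              "included",
            class = c("sliding_profile", "data.frame"))
}

#' Call an ecotone transition interval and boundary from a profile
#'
#' The transition interval is the maximal contiguous run of comparisons whose
#' shared-species index falls strictly below a profile-relative threshold
#' (the \code{low_quantile} quantile of the shared-index distribution, or an
#' absolute override). The boundary is placed where the exclusivity balance
#' (below-exclusive minus above-exclusive) changes sign: at a comparison edge
#' if the balance is exactly zero there, otherwise at the midpoint of the bin
#' separating the last negative and first positive comparisons; among several
#' sign changes the one nearest the transition interval's centre is used. If
#' no sign change exists, the boundary falls back to the minimum-shared-index
#' edge with a low-confidence note.
#'
#' @param profile a \code{sliding_profile} with >= 3 comparisons.
#' @param low_quantile quantile defining "low" shared index (default 0.25).
#' @param absolute_threshold optional absolute shared-index threshold
#'   overriding the quantile rule.
#' @return List of class \code{ecotone_call}: \code{detected},
#'   \code{transition_interval}, \code{boundary}, \code{diagnostics},
#'   \code{confidence_note}.
#' @export
detect_ecotone <- function(profile, low_quantile = 0.25,
                           absolute_threshold = NULL) {
  stopifnot(inherits(profile, "sliding_profile"))
  if (nrow(profile) < 3L) stop("profile needs at least 3 comparisons")
  s <- profile$shared_index
  thr <- if (!is.null(absolute_threshold)) absolute_threshold else
    unname(stats::quantile(s, low_quantile, na.rm = TRUE))
  # <= with a strict-below-maximum guard: robust to ties at the minimum
  # (sparse profiles) while a flat profile still yields "no ecotone"
  low <- !is.na(s) & s <= thr & s < max(s, na.rm = TRUE)
  if (!any(low)) {
    return(structure(list(detected = FALSE, transition_interval = NULL,
                          boundary = NA_real_,
                          diagnostics = list(threshold = thr,
                                             min_shared = min(s, na.rm = TRUE)),
                          confidence_note = "no ecotone detected"),
                     class = "ecotone_call"))
  }
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  len <- runs$lengths[cand]
  # longest low run; ties resolved in favour of the run holding the minimum
  best <- cand[len == max(len)]
  if (length(best) > 1L) {
    holds_min <- vapply(best, function(r) {
      idx <- starts[r]:ends[r]
      min(s[idx]) == min(s[low])
    }, logical(1))
    best <- if (any(holds_min)) best[holds_min][1] else best[1]
  }
  run_idx <- starts[best]:ends[best]
  interval <- c(profile$boundary_elev[run_idx[1]],
                profile$boundary_elev[run_idx[length(run_idx)]])

  D <- profile$below_exclusive - profile$above_exclusive
  edges <- profile$boundary_elev
  cands <- numeric(0)
  for (i in seq_along(D)) {
    if (D[i] == 0) cands <- c(cands, edges[i])
    if (i < length(D) && sign(D[i]) < 0 && sign(D[i + 1]) > 0)
      cands <- c(cands, (edges[i] + edges[i + 1]) / 2)
  }
  centre <- mean(interval)
  if (length(cands)) {
    boundary <- cands[which.min(abs(cands - centre))]
    note <- "boundary at exclusivity-balance sign change"
    interval <- c(min(interval[1], boundary), max(interval[2], boundary))
  } else {
    boundary <- edges[which.min(s)]
    note <- paste("low confidence: no exclusivity sign change;",
                  "boundary at minimum shared index")
    interval <- c(min(interval[1], boundary), max(interval[2], boundary))
  }
  structure(list(detected = TRUE, transition_interval = interval,
                 boundary = boundary,
                 diagnostics = list(threshold = thr,
                                    min_shared = min(s, na.rm = TRUE),
                                    exclusivity_balance = D),
                 confidence_note = note),
            class = "ecotone_call")
}

#' @export
print.ecotone_call <- function(x, ...) {
  if (!x$detected) {
    cat("<ecotone_call> no ecotone detected\n")
  } else {
    cat(sprintf("<ecotone_call> boundary %.0f m, transition %.0f-%.0f m (%s)\n",
                x$boundary, x$transition_interval[1],
                x$transition_interval[2], x$confidence_note))
  }
  invisible(x)
}

#' Bin-width sensitivity scan for the sliding-window procedure
#'
#' Re-runs slicing, profiling and detection over a set of candidate bin
#' widths, returning the called boundary per width. A helper for choosing
#' the width; no automatic selection is attempted.
#'
#' @param table a \code{specimen_table}.
#' @param hypothesis species-hypothesis name.
#' @param widths candidate widths in metres.
#' @param ... passed to \code{\link{sliding_profile}} and
#'   \code{\link{detect_ecotone}}.
#' @return data.frame \code{width}, \code{boundary}, \code{detected}.
#' @export
ecotone_width_scan <- function(table, hypothesis,
                               widths = c(20, 40, 60, 80), ...) {
  res <- lapply(widths, function(w) {
    call <- tryCatch(
      detect_ecotone(sliding_profile(slice_elevation(table, w), hypothesis,
                                     ...)),
      error = function(e) NULL)
    data.frame(width = w,
               boundary = if (is.null(call)) NA_real_ else call$boundary,
               detected = !is.null(call) && isTRUE(call$detected))
  })
  do.call(rbind, res)
}
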