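#' Incidence frequency counts
#'
#' Tallies, for an incidence matrix, the number of species found in exactly
#' k sample-units: Q1 (uniques), Q2 (duplicates), and so on. These counts,
#' together with the number of units m and the observed richness S_obs, feed
#' every nonparametric richness estimator.
#'
#' @param X an \code{incidence_matrix} (or any 0/1 matrix, species x units).
#' @return List of class \code{frequency_counts}: \code{S_obs}, \code{m},
#'   \code{Q} (named vector, \code{Q[k]} = species in exactly k units),
#'   \code{counts} (per-species unit counts), \code{total_incidences}.
#' @export
incidence_frequencies <- function(X) {
  if (is.null(dim(X)) || nrow(X) == 0L || ncol(X) == 0L)
    stop("empty incidence matrix")
  counts <- rowSums(X > 0)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty incidence matrix (no incidences)")
  m <- ncol(X)
  Q <- tabulate(counts, nbins = m)
  names(Q) <- seq_len(m)
  structure(list(S_obs = length(counts), m = m, Q = Q,
                 counts = as.numeric(counts),
                 total_incidences = sum(counts)),
            class = "frequency_counts")
}

as_frequency_counts <- function(x) {
  if (inherits(x, "frequency_counts")) x else incidence_frequencies(x)
}

#' Chao2 incidence-based richness estimator
#'
#' Classic form \eqn{S_{obs} + \frac{m-1}{m}\frac{Q_1^2}{2Q_2}} or
#' bias-corrected form \eqn{S_{obs} + \frac{m-1}{m}\frac{Q_1(Q_1-1)}{2(Q_2+1)}}.
#' In \code{mode = "auto"} the bias-corrected form is used unless the
#' coefficient of variation (sd/mean) of the per-species incidence counts
#' exceeds \code{cv_threshold}, in which case the classic form is used.
#' When Q2 = 0 the classic form is undefined and the bias-corrected form is
#' substituted. The standard deviation follows Chao's incidence variance
#' formulas.
#'
#' @param x a \code{frequency_counts} or an incidence matrix.
#' @param mode \code{"auto"}, \code{"classic"} or \code{"bias_corrected"}.
#' @param cv_threshold CV switch point for \code{mode = "auto"} (default 0.5).
#' @return List of class \code{richness_estimate}: \code{estimator},
#'   \code{value}, \code{sd}, \code{mode_notes}.
#' @export
chao2 <- function(x, mode = c("auto", "classic", "bias_corrected"),
                  cv_threshold = 0.5) {
  mode <- match.arg(mode)
  fc <- as_frequency_counts(x)
  if (fc$m < 2L) stop("Chao2 requires at least 2 sample-units")
  S <- fc$S_obs; m <- fc$m
  Q1 <- fc$Q[1]; Q2 <- if (m >= 2) fc$Q[2] else 0
  A <- (m - 1) / m
  cv <- if (mean(fc$counts) > 0) stats::sd(fc$counts) / mean(fc$counts) else 0
  use <- switch(mode,
    classic = "classic",
    bias_corrected = "bias_corrected",
    auto = if (cv > cv_threshold) "classic" else "bias_corrected")
  note <- if (mode == "auto")
    sprintf("auto: CV=%.3f %s %.2f -> %s", cv,
            if (cv > cv_threshold) ">" else "<=", cv_threshold, use)
  else use
  if (Q1 == 0) {
    return(new_richness_estimate("Chao2", S, 0,
                                 paste0(note, "; Q1=0, estimate = S_obs")))
  }
  if (use == "classic" && Q2 == 0) {
    use <- "bias_corrected"
    note <- paste0(note, "; Q2=0, bias-corrected form substituted")
  }
  if (use == "classic") {
    est <- S + A * Q1^2 / (2 * Q2)
    r <- Q1 / Q2
    v <- Q2 * (A / 2 * r^2 + A^2 * r^3 + A^2 / 4 * r^4)
  } else {
    est <- S + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
    v <- A * Q1 * (Q1 - 1) / (2 * (Q2 + 1)) +
      A^2 * Q1 * (2 * Q1 - 1)^2 / (4 * (Q2 + 1)^2) +
      A^2 * Q1^2 * Q2 * (Q1 - 1)^2 / (4 * (Q2 + 1)^4)
  }
  new_richness_estimate(paste0("Chao2-", sub("bias_corrected", "bc", use)),
                        est, sqrt(max(v, 0)), note)
}

#' ICE: incidence-based coverage estimator
#'
#' Species are split at \code{frequency_cutoff} into frequent (found in more
#' than the cutoff number of units) and infrequent groups. With
#' \eqn{C_{ice} = 1 - Q_1/N_{inf}} the sample coverage of the infrequent
#' group, the estimate is
#' \eqn{S_{freq} + S_{inf}/C_{ice} + (Q_1/C_{ice})\gamma^2_{ice}}, where the
#' squared CV term follows Lee and Chao. If all infrequent incidences are
#' uniques (coverage zero), the bias-corrected Chao2 is returned instead with
#' a note.
#'
#' @param X incidence matrix (species x units).
#' @param frequency_cutoff infrequent/frequent split (default 10 units).
#' @return A \code{richness_estimate}.
#' @export
ice <- function(X, frequency_cutoff = 10) {
  fc <- incidence_frequencies(X)
  if (fc$m < 2L) stop("ICE requires at least 2 sample-units")
  counts <- rowSums(X > 0)
  counts <- counts[counts > 0]
  infreq <- counts <= frequency_cutoff
  S_freq <- sum(!infreq)
  S_inf <- sum(infreq)
  if (S_inf == 0)
    return(new_richness_estimate("ICE", fc$S_obs, NA_real_,
                                 "all species frequent; ICE = S_obs"))
  N_inf <- sum(counts[infreq])
  Q1 <- sum(counts == 1)
  C_ice <- 1 - Q1 / N_inf
  if (C_ice <= 0) {
    est <- chao2(fc, mode = "bias_corrected")
    est$estimator <- "ICE"
    est$mode_notes <- "C_ice = 0; Chao2 bias-corrected fallback"
    return(est)
  }
  # units containing at least one infrequent species
  m_inf <- sum(colSums(X[infreq, , drop = FALSE] > 0) > 0)
  ks <- seq_len(min(frequency_cutoff, fc$m))
  sum_kk1 <- sum(ks * (ks - 1) * fc$Q[ks])
  gamma2 <- if (m_inf > 1)
    max(S_inf / C_ice * m_inf / (m_inf - 1) * sum_kk1 / N_inf^2 - 1, 0) else 0
  est <- S_freq + S_inf / C_ice + Q1 / C_ice * gamma2
  new_richness_estimate("ICE", est, NA_real_,
                        sprintf("cutoff=%d, C_ice=%.4f, gamma2=%.4f",
                                frequency_cutoff, C_ice, gamma2))
}

#' First- and second-order jackknife richness estimators
#'
#' Jack1 \eqn{= S_{obs} + Q_1 (m-1)/m}; Jack2
#' \eqn{= S_{obs} + Q_1(2m-3)/m - Q_2 (m-2)^2 / (m(m-1))}.
#'
#' @param x a \code{frequency_counts} or incidence matrix.
#' @param order 1 or 2.
#' @return A \code{richness_estimate}.
#' @export
jackknife <- function(x, order = 1) {
  fc <- as_frequency_counts(x)
  S <- fc$S_obs; m <- fc$m
  Q1 <- fc$Q[1]; Q2 <- if (m >= 2) fc$Q[2] else 0
  if (order == 1) {
    if (m < 2L) stop("Jack1 requires m >= 2")
    est <- S + Q1 * (m - 1) / m
    new_richness_estimate("Jack1", est, jack1_variance(x, fc), NULL)
  } else if (order == 2) {
    if (m < 3L) stop("Jack2 requires m >= 3")
    est <- S + Q1 * (2 * m - 3) / m - Q2 * (m - 2)^2 / (m * (m - 1))
    new_richness_estimate("Jack2", est, NA_real_, NULL)
  } else stop("order must be 1 or 2")
}

# Heltshe & Forrester variance; needs the full matrix, NA from counts alone
jack1_variance <- function(x, fc) {
  if (inherits(x, "frequency_counts") || is.null(dim(x))) return(NA_real_)
  m <- ncol(x)
  uniques_per_unit <- colSums((x > 0) & (rowSums(x > 0) == 1))
  Q1 <- sum(rowSums(x > 0) == 1)
  sqrt(max(0, (m - 1) / m * (sum(uniques_per_unit^2) - Q1^2 / m)))
}

new_richness_estimate <- function(estimator, value, sd, mode_notes) {
  structure(list(estimator = estimator, value = as.numeric(value),
                 sd = if (is.null(sd)) NA_real_ else as.numeric(sd),
                 mode_notes = mode_notes),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("%s: %.1f", x$estimator, x$value))
  if (!is.na(x$sd)) cat(sprintf(" ± %.2f", x$sd))
  if (!is.null(x$mode_notes)) cat("  [", x$mode_notes, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Sample-based rarefaction and extrapolation
#'
#' Interpolation uses the exact hypergeometric expectation
#' \eqn{E[S(t)] = S_{obs} - \sum_s \binom{m - m_s}{t} / \binom{m}{t}};
#' extrapolation to \eqn{t = m + m^*} uses
#' \eqn{S_{obs} + \hat{Q}_0 [1 - (1 - Q_1 / (Q_1 + m \hat{Q}_0))^{m^*}]}
#' with \eqn{\hat{Q}_0} the Chao2 unseen-species estimate. Standard
#' deviations come from a bootstrap over sample-units.
#'
#' @param X incidence matrix (species x units).
#' @param target_factor extrapolate to \code{target_factor * m} units
#'   (default 3).
#' @param n_boot bootstrap replicates for the sd (default 100).
#' @param seed seed for the bootstrap.
#' @return List of class \code{rarefaction_curve}: \code{curve} (data.frame
#'   \code{t}, \code{S}, \code{sd}) and \code{estimate_at_target} (a
#'   \code{richness_estimate}).
#' @export
rarefy_extrapolate <- function(X, target_factor = 3, n_boot = 100,
                               seed = NULL) {
  fc <- incidence_frequencies(X)
  m <- fc$m
  if (m < 2L) stop("rarefaction requires at least 2 sample-units")
  if (target_factor < 1) stop("target_factor must be >= 1")
  t_max <- ceiling(target_factor * m)
  ts <- seq_len(t_max)
  S_hat <- rarefaction_values(X, ts)
  sds <- rep(NA_real_, length(ts))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, length(ts))
    for (b in seq_len(n_boot)) {
      Xb <- X[, sample.int(m, m, replace = TRUE), drop = FALSE]
      Xb <- Xb[rowSums(Xb > 0) > 0, , drop = FALSE]
      if (nrow(Xb) == 0) next
      boot[b, ] <- rarefaction_values(Xb, ts)
    }
    sds <- apply(boot, 2, stats::sd, na.rm = TRUE)
  }
  curve <- data.frame(t = ts, S = S_hat, sd = sds)
  est <- new_richness_estimate(
    sprintf("Rarefaction%gx", target_factor),
    S_hat[t_max], sds[t_max],
    sprintf("m=%d, target t=%d, %d bootstrap replicates", m, t_max, n_boot))
  structure(list(curve = curve, estimate_at_target = est),
            class = "rarefaction_curve")
}

# E[S(t)] for t <= m (exact) and extrapolated S for t > m (Chao2-based)
rarefaction_values <- function(X, ts) {
  counts <- rowSums(X > 0)
  counts <- counts[counts > 0]
  m <- ncol(X)
  S <- length(counts)
  Q1 <- sum(counts == 1)
  Q2 <- sum(counts == 2)
  A <- (m - 1) / m
  Q0 <- if (Q2 > 0) A * Q1^2 / (2 * Q2) else A * Q1 * (Q1 - 1) / 2
  vapply(ts, function(t) {
    if (t <= m) {
      # sum of C(m - m_s, t) / C(m, t) on log scale for stability
      keep <- (m - counts) >= t
      if (!any(keep)) return(S)
      lr <- lchoose(m - counts[keep], t) - lchoose(m, t)
      S - sum(exp(lr))
    } else {
      if (Q0 <= 0 || Q1 == 0) return(S)
      S + Q0 * (1 - (1 - Q1 / (Q1 + m * Q0))^(t - m))
    }
  }, numeric(1))
}

#' Richness estimate table for one incidence matrix
#'
#' Convenience wrapper computing the standard battery (rarefaction to a
#' target factor, ICE, Chao2 in auto mode, Jack1, Jack2) in one call.
#'
#' @param X incidence matrix.
#' @param target_factor rarefaction/extrapolation factor (default 3).
#' @param n_boot bootstrap replicates for the rarefaction sd.
#' @param seed bootstrap seed.
#' @return data.frame with columns \code{estimator}, \code{value}, \code{sd},
#'   \code{notes}; values rounded to 1 decimal, sd to 2.
#' @export
richness_table <- function(X, target_factor = 3, n_boot = 100, seed = NULL) {
  fc <- incidence_frequencies(X)
  ests <- list(
    rarefy_extrapolate(X, target_factor, n_boot, seed)$estimate_at_target,
    ice(X), chao2(fc), jackknife(X, 1),
    if (fc$m >= 3) jackknife(X, 2) else NULL)
  ests <- Filter(Negate(is.null), ests)
  data.frame(
    estimator = vapply(ests, `[[`, "", "estimator"),
    value = round(vapply(ests, `[[`, 0, "value"), 1),
    sd = round(vapply(ests, `[[`, 0, "sd"), 2),
    notes = vapply(ests, function(e)
      if (is.null(e$mode_notes)) "" else e$mode_notes, ""),
    stringsAsFactors = FALSE)
}
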