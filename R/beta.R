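#' Baselga partition of pairwise beta diversity
#'
#' Decomposes total Sorensen dissimilarity into a turnover component
#' (Simpson dissimilarity, species replacement independent of richness
#' difference) and a nestedness-resultant component:
#' \eqn{\beta_{sor} = (b+c)/(2a+b+c)},
#' \eqn{\beta_{sim} = \min(b,c)/(a+\min(b,c))},
#' \eqn{\beta_{sne} = \beta_{sor} - \beta_{sim}}. The identity
#' total = turnover + nestedness is exact.
#'
#' @param pc a \code{pair_counts}.
#' @return List of class \code{beta_decomposition}: \code{family},
#'   \code{total}, \code{turnover}, \code{nestedness_or_richness},
#'   \code{scope}.
#' @export
baselga_pair <- function(pc) {
  with(pc, {
    if (a + b + c == 0) stop("beta undefined: both communities empty")
    bsor <- (b + c) / (2 * a + b + c)
    bsim <- if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
    new_beta("baselga_sorensen", bsim, bsor - bsim, "pairwise")
  })
}

#' Baselga multiple-site partition
#'
#' Multiple-site Sorensen dissimilarity and its Simpson (turnover) and
#' nestedness components over all units of an incidence matrix. With
#' \eqn{b_{ij}} the number of species present in site i but not j:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
#'   {\sum_i S_i - S_T + \sum_{i<j}\min(b_{ij},b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum\min + \sum\max}
#'   {2(\sum_i S_i - S_T) + \sum\min + \sum\max}}
#' and \eqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}.
#'
#' @param X incidence matrix (species x units), >= 2 units.
#' @return A \code{beta_decomposition} with multisite scope.
#' @export
baselga_multisite <- function(X) {
  if (ncol(X) < 2L) stop("multisite beta requires at least 2 units")
  P <- t(X > 0) * 1L              # units x species
  n <- nrow(P)
  Si <- rowSums(P)
  ST <- sum(colSums(P) > 0)
  shared <- P %*% t(P)            # a_ij
  bmat <- Si - shared             # b_ij = species in i not in j
  iu <- which(upper.tri(bmat), arr.ind = TRUE)
  bij <- bmat[iu]
  bji <- t(bmat)[iu]
  smin <- sum(pmin(bij, bji))
  smax <- sum(pmax(bij, bji))
  core <- sum(Si) - ST
  bsim <- if (core + smin == 0) 0 else smin / (core + smin)
  bsor <- if (2 * core + smin + smax == 0) 0 else
    (smin + smax) / (2 * core + smin + smax)
  new_beta("baselga_sorensen", bsim, bsor - bsim,
           sprintf("multisite(%d sites)", n))
}

#' Carvalho partition into replacement and richness difference
#'
#' The alternative decomposition of total dissimilarity into species
#' replacement and richness-difference components. Jaccard family (default):
#' \eqn{\beta_{cc} = (b+c)/(a+b+c)},
#' \eqn{\beta_{repl} = 2\min(b,c)/(a+b+c)},
#' \eqn{\beta_{rich} = |b-c|/(a+b+c)}; the Sorensen family replaces the
#' denominator by \eqn{2a+b+c}. total = replacement + richness exactly.
#'
#' @param pc a \code{pair_counts}.
#' @param family \code{"jaccard"} (default) or \code{"sorensen"}.
#' @return A \code{beta_decomposition}.
#' @export
carvalho_pair <- function(pc, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  with(pc, {
    if (a + b + c == 0) stop("beta undefined: both communities empty")
    den <- if (family == "jaccard") a + b + c else 2 * a + b + c
    new_beta(paste0("carvalho_", family),
             2 * min(b, c) / den, abs(b - c) / den, "pairwise")
  })
}

#' Carvalho multiple-site partition (mean over pairs)
#'
#' Multiple-site values are taken as the arithmetic mean of the pairwise
#' components over all unit pairs (one of several variants in circulation;
#' flagged in the scope metadata). Additivity is preserved exactly.
#'
#' @param X incidence matrix, >= 2 units.
#' @param family \code{"jaccard"} or \code{"sorensen"}.
#' @return A \code{beta_decomposition}.
#' @export
carvalho_multisite <- function(X, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  if (ncol(X) < 2L) stop("multisite beta requires at least 2 units")
  n <- ncol(X)
  comps <- matrix(0, 0, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- carvalho_pair(pair_counts(X[, i], X[, j]), family)
    comps <- rbind(comps, c(d$total, d$turnover, d$nestedness_or_richness))
  }
  mu <- colMeans(comps)
  new_beta(paste0("carvalho_", family), mu[2], mu[3],
           sprintf("multisite(%d sites, mean over pairs)", n))
}

# total is stored as turnover + rest, so the additivity identity
# total = turnover + nestedness_or_richness holds bit-exactly by construction
new_beta <- function(family, turnover, rest, scope) {
  structure(list(family = family, total = turnover + rest,
                 turnover = turnover, nestedness_or_richness = rest,
                 scope = scope),
            class = "beta_decomposition")
}

#' @export
print.beta_decomposition <- function(x, ...) {
  lab <- if (grepl("baselga", x$family)) c("turnover", "nestedness")
  else c("replacement", "richness")
  cat(sprintf("%s [%s]: total %.3f = %s %.3f + %s %.3f\n", x$family,
              x$scope, x$total, lab[1], x$turnover, lab[2],
              x$nestedness_or_richness))
  invisible(x)
}

#' Fraction of total dissimilarity due to turnover
#'
#' @param d a \code{beta_decomposition} with positive total.
#' @return turnover / total, in [0, 1].
#' @export
turnover_fraction <- function(d) {
  if (d$total <= 0) stop("turnover fraction undefined: total dissimilarity 0")
  d$turnover / d$total
}

#' UPGMA clustering of communities
#'
#' Average-linkage agglomeration of a symmetric dissimilarity matrix, with a
#' deterministic tie-break: among equally close cluster pairs, the pair
#' whose (lexicographically sorted) member labels come first is merged.
#' Returned as an \code{hclust}-compatible object (heights are merge
#' heights; plot, \code{stats::cophenetic} and \code{ape::as.phylo} all
#' work). Single and complete linkage are available as alternates.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (or a
#'   \code{dist}).
#' @param linkage \code{"average"} (UPGMA, default), \code{"single"} or
#'   \code{"complete"}.
#' @return Object of classes \code{upgma} and \code{hclust}.
#' @export
upgma <- function(D, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-10))
    stop("dissimilarity matrix must be symmetric")
  if (any(diag(D) != 0)) stop("dissimilarity matrix must have zero diagonal")
  n <- nrow(D)
  labels <- if (is.null(rownames(D))) as.character(seq_len(n)) else
    rownames(D)
  # active clusters: id (<0 leaf, >0 merge row), size, member labels
  id <- -seq_len(n)
  size <- rep(1L, n)
  members <- as.list(labels)
  d <- D
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    nb <- length(id)
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      key <- paste(sort(c(members[[i]], members[[j]]))[1:2], collapse = "\r")
      if (d[i, j] < bestd - 1e-12 ||
          (abs(d[i, j] - bestd) <= 1e-12 &&
           (is.null(bestkey) || key < bestkey))) {
        bestd <- d[i, j]; best <- c(i, j); bestkey <- key
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd
    # linkage update against every other cluster
    others <- setdiff(seq_len(nb), c(i, j))
    newrow <- vapply(others, function(k) {
      switch(linkage,
             average = (size[i] * d[i, k] + size[j] * d[j, k]) /
               (size[i] + size[j]),
             single = min(d[i, k], d[j, k]),
             complete = max(d[i, k], d[j, k]))
    }, numeric(1))
    keep_id <- c(id[others], step)
    keep_size <- c(size[others], size[i] + size[j])
    keep_members <- c(members[others],
                      list(sort(c(members[[i]], members[[j]]))))
    nd <- matrix(0, length(others) + 1, length(others) + 1)
    if (length(others)) {
      nd[seq_along(others), seq_along(others)] <-
        d[others, others, drop = FALSE]
      nd[length(others) + 1, seq_along(others)] <- newrow
      nd[seq_along(others), length(others) + 1] <- newrow
    }
    id <- keep_id; size <- keep_size; members <- keep_members; d <- nd
  }
  out <- structure(list(merge = merge, height = height,
                        order = upgma_order(merge, n),
                        labels = labels, method = linkage,
                        call = match.call(),
                        dist.method = "user-supplied"),
                   class = c("upgma", "hclust"))
  out
}

upgma_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are assigned ultrametrically: each leaf sits at depth half
#' its cluster's merge height (the conventional height-halving for
#' UPGMA trees).
#'
#' @param h an \code{hclust}-like object (e.g. from \code{\link{upgma}}).
#' @param file optional path; when given the tree is also written there.
#' @return Newick string, invisibly when writing to file.
#' @export
as_newick <- function(h, file = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(h))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Distance decay of compositional similarity
#'
#' Computes, for every pair of sample-units with coordinates, the
#' great-circle distance and the compositional similarity, fits an ordinary
#' least-squares line, and adds a moving-window least-squares smooth
#' (window = a fixed fraction of the pairs, ordered by distance).
#'
#' @param table a \code{specimen_table}.
#' @param hypothesis species-hypothesis name.
#' @param unit sample-unit definition (default \code{"locality"}).
#' @param index \code{"sorensen"} or \code{"jaccard"}.
#' @param window_frac fraction of pairs in each local-fit window
#'   (default 0.25).
#' @return List of class \code{distance_decay}: \code{pairs} (data.frame
#'   \code{unit1}, \code{unit2}, \code{km}, \code{similarity}), \code{fit}
#'   (intercept, slope), \code{smooth} (data.frame \code{km},
#'   \code{similarity}).
#' @export
distance_decay <- function(table, hypothesis, unit = "locality",
                           index = c("sorensen", "jaccard"),
                           window_frac = 0.25) {
  index <- match.arg(index)
  X <- build_incidence(table, hypothesis, unit)
  if (ncol(X) < 3L) stop("distance decay requires at least 3 units")
  key <- if (unit == "path") "path" else "locality"
  coords <- unique(as.data.frame(table)[, c(key, "latitude", "longitude")])
  coords <- stats::aggregate(coords[, c("latitude", "longitude")],
                             by = list(unit = coords[[key]]), mean)
  coords <- coords[match(colnames(X), coords$unit), ]
  M <- similarity_matrix(X, index)
  iu <- which(upper.tri(M), arr.ind = TRUE)
  km <- great_circle_km(coords$latitude[iu[, 1]], coords$longitude[iu[, 1]],
                        coords$latitude[iu[, 2]], coords$longitude[iu[, 2]])
  pairs <- data.frame(unit1 = colnames(X)[iu[, 1]],
                      unit2 = colnames(X)[iu[, 2]],
                      km = km, similarity = M[iu])
  if (stats::var(pairs$km) == 0)
    stop("distance decay fit undefined: all pairwise distances identical")
  fit <- stats::lm(similarity ~ km, data = pairs)
  o <- order(pairs$km)
  w <- max(3L, floor(window_frac * nrow(pairs)))
  sm <- t(vapply(seq_len(nrow(pairs)), function(k) {
    idx <- o[max(1, k - w %/% 2):min(nrow(pairs), k + w %/% 2)]
    x <- pairs$km[idx]; y <- pairs$similarity[idx]
    yhat <- if (stats::var(x) == 0) mean(y) else {
      cf <- stats::coef(stats::lm(y ~ x))
      cf[1] + cf[2] * pairs$km[o[k]]
    }
    c(pairs$km[o[k]], yhat)
  }, numeric(2)))
  structure(list(pairs = pairs,
                 fit = list(intercept = unname(stats::coef(fit)[1]),
                            slope = unname(stats::coef(fit)[2])),
                 smooth = data.frame(km = sm[, 1], similarity = sm[, 2])),
            class = "distance_decay")
}
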