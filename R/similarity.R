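#' Pairwise species-set counts
#'
#' Splits two communities' species sets into shared (a) and exclusive (b, c)
#' counts, the triple underlying Sorensen/Jaccard similarity and every beta
#' partition.
#'
#' @param x,y species sets: character vectors, or named 0/1 vectors
#'   (incidence-matrix columns).
#' @return List of class \code{pair_counts}: \code{a}, \code{b}, \code{c}.
#' @export
pair_counts <- function(x, y) {
  sx <- as_species_set(x)
  sy <- as_species_set(y)
  a <- length(intersect(sx, sy))
  new_pair_counts(a, length(sx) - a, length(sy) - a)
}

as_species_set <- function(x) {
  if (is.numeric(x) || is.logical(x)) {
    if (is.null(names(x))) names(x) <- seq_along(x)
    unique(names(x)[x > 0])
  } else unique(as.character(x))
}

new_pair_counts <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c)),
            class = "pair_counts")
}

#' Sorensen and Jaccard similarity
#'
#' Sorensen-Dice \eqn{2a/(2a+b+c)} and Jaccard \eqn{a/(a+b+c)} from shared
#' and exclusive species counts. Both error on two empty communities.
#'
#' @param pc a \code{pair_counts} (or list with \code{a}, \code{b}, \code{c}).
#' @return Similarity in [0, 1].
#' @export
sorensen_similarity <- function(pc) {
  with(pc, {
    if (a + b + c == 0) stop("similarity undefined: both communities empty")
    2 * a / (2 * a + b + c)
  })
}

#' @rdname sorensen_similarity
#' @export
jaccard_similarity <- function(pc) {
  with(pc, {
    if (a + b + c == 0) stop("similarity undefined: both communities empty")
    a / (a + b + c)
  })
}

#' Convert a Sorensen similarity to Jaccard
#'
#' The two indices are linked by the identity \eqn{J = S / (2 - S)}.
#'
#' @param S Sorensen similarity in [0, 1].
#' @return Jaccard similarity.
#' @export
jaccard_from_sorensen <- function(S) {
  if (any(S < 0 | S > 1)) stop("Sorensen similarity must be in [0, 1]")
  S / (2 - S)
}

#' Infer the integer shared-species count behind a printed similarity
#'
#' Published community tables often print per-site richness and a Sorensen
#' similarity but not the shared-species count a. Since
#' \eqn{S = 2a/(S_1 + S_2)}, a is recovered as
#' \eqn{round(S (S_1 + S_2)/2)} (ties round half-up), clamped to
#' \eqn{[0, \min(S_1, S_2)]}. From a the exact Jaccard value can be
#' reconstructed.
#'
#' @param S1,S2 per-community species richness (>= 1).
#' @param sorensen printed Sorensen similarity in [0, 1].
#' @return Integer shared-species count.
#' @export
infer_shared_count <- function(S1, S2, sorensen) {
  stopifnot(S1 >= 1, S2 >= 1)
  if (sorensen < 0 || sorensen > 1) stop("sorensen must be in [0, 1]")
  a <- floor(sorensen * (S1 + S2) / 2 + 0.5)   # round half-up
  as.integer(min(max(a, 0), min(S1, S2)))
}

#' Pairwise similarity matrix over the units of an incidence matrix
#'
#' @param X incidence matrix (species x units), >= 2 units.
#' @param index \code{"sorensen"} or \code{"jaccard"}.
#' @return Symmetric matrix of similarities with unit diagonal, labelled by
#'   unit, attribute \code{index} set.
#' @export
similarity_matrix <- function(X, index = c("sorensen", "jaccard")) {
  index <- match.arg(index)
  if (ncol(X) < 2L) stop("similarity_matrix requires at least 2 units")
  n <- ncol(X)
  M <- diag(1, n)
  dimnames(M) <- list(colnames(X), colnames(X))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pc <- pair_counts(X[, i], X[, j])
    M[i, j] <- M[j, i] <- if (index == "sorensen")
      sorensen_similarity(pc) else jaccard_similarity(pc)
  }
  attr(M, "index") <- index
  M
}

#' Published per-path summaries of the Nui Chua survey
#'
#' Accessors for the printed per-path species richness (morphospecies and
#' bPTP delimitation) and the printed Sorensen/Jaccard path-pair similarity
#' table of the Nui Chua leaf-beetle survey, used as reconstruction inputs
#' and test fixtures.
#'
#' @return \code{nui_chua_path_richness}: data.frame \code{path},
#'   \code{species_morpho}, \code{species_bptp}.
#'   \code{nui_chua_path_similarity}: data.frame \code{path1}, \code{path2},
#'   \code{sorensen}, \code{jaccard}.
#' @export
nui_chua_path_richness <- function() {
  utils::read.csv(system.file("extdata", "nui_chua_path_summary.csv",
                              package = "betagrad", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname nui_chua_path_richness
#' @export
nui_chua_path_similarity <- function() {
  utils::read.csv(system.file("extdata", "nui_chua_path_similarity.csv",
                              package = "betagrad", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
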