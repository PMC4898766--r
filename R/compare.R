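#' Score agreement between two species partitions of the same specimens
#'
#' Classifies every reference species (its set of specimens) by its relation
#' to the test partition:
#' \itemize{
#'   \item \strong{agree}: the specimen set equals exactly one test species;
#'   \item \strong{split}: partitioned into two or more test species, all of
#'     them wholly inside the reference species;
#'   \item \strong{merge}: wholly contained, together with at least one other
#'     complete reference species, in a single test species (every reference
#'     species involved in such a union is counted as merged);
#'   \item \strong{complex}: any remaining many-to-many overlap.
#' }
#' The four classes are mutually exclusive and exhaustive, so their counts
#' sum to the number of reference species. Rows missing either label are
#' dropped with a message.
#'
#' @param table a \code{specimen_table}.
#' @param reference,test species-hypothesis names.
#' @param collapse_haplotypes compare on haplotypes (one vote per haplotype)
#'   and re-expand, instead of on individuals (default FALSE).
#' @return List of class \code{partition_comparison}: \code{reference},
#'   \code{test}, \code{n_reference}, \code{agree}, \code{split},
#'   \code{merge}, \code{complex}, and \code{classes} (named character vector
#'   per reference species).
#' @export
compare_partitions <- function(table, reference, test,
                               collapse_haplotypes = FALSE) {
  ref <- species_column(table, reference)
  tst <- species_column(table, test)
  ids <- as.character(table$specimen_id)
  if (collapse_haplotypes) {
    if (!"haplotype" %in% names(table))
      stop("collapse_haplotypes requires a haplotype column")
    ids <- as.character(table$haplotype)
  }
  keep <- !is.na(ref) & !is.na(tst)
  if (any(!keep))
    message(sum(!keep), " record(s) missing a label under one hypothesis ",
            "dropped")
  if (!any(keep)) stop("empty overlap universe between the two hypotheses")
  ref <- ref[keep]; tst <- tst[keep]; ids <- ids[keep]
  if (collapse_haplotypes) {
    first <- !duplicated(ids)
    ref <- ref[first]; tst <- tst[first]; ids <- ids[first]
  }
  ref_sets <- split(ids, ref)
  tst_sets <- split(ids, tst)
  tst_of <- stats::setNames(tst, ids)
  ref_of <- stats::setNames(ref, ids)
  classes <- vapply(names(ref_sets), function(r) {
    Sr <- ref_sets[[r]]
    ts <- unique(tst_of[Sr])
    if (length(ts) == 1L) {
      Tset <- tst_sets[[ts]]
      if (setequal(Tset, Sr)) return("agree")
      # Sr strictly inside Tset: merge iff Tset is a union of complete
      # reference species
      rs <- unique(ref_of[Tset])
      whole <- all(vapply(rs, function(rr)
        all(ref_sets[[rr]] %in% Tset), logical(1)))
      return(if (whole) "merge" else "complex")
    }
    if (all(vapply(ts, function(tt) all(tst_sets[[tt]] %in% Sr),
                   logical(1)))) return("split")
    "complex"
  }, character(1))
  structure(list(reference = reference, test = test,
                 n_reference = length(ref_sets),
                 agree = sum(classes == "agree"),
                 split = sum(classes == "split"),
                 merge = sum(classes == "merge"),
                 complex = sum(classes == "complex"),
                 classes = classes),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf(
    "<partition_comparison> %s vs %s: %d reference species | agree %d, split %d, merge %d, complex %d (match %.1f%%)\n",
    x$reference, x$test, x$n_reference, x$agree, x$split, x$merge,
    x$complex, match_percentage(x)))
  invisible(x)
}

#' Percentage of reference species perfectly recovered
#'
#' @param cmp a \code{partition_comparison} (or list with \code{agree} and
#'   \code{n_reference}).
#' @return 100 * agree / n_reference.
#' @export
match_percentage <- function(cmp) {
  if (cmp$n_reference <= 0) stop("no reference species")
  100 * cmp$agree / cmp$n_reference
}
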