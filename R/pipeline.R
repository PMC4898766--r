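#' Run the full gradient-community analysis pipeline
#'
#' Orchestrates the whole analysis from one configuration: specimen input
#' (file or synthetic generator), incidence matrices over the requested unit
#' definitions, richness-estimate table, similarity matrices, beta-diversity
#' partitions with UPGMA dendrograms, sliding-window ecotone profile and
#' call, optional delimitation comparison, and a run log. All randomness
#' (generator, bootstrap) derives from one root seed with fixed per-stage
#' offsets, so stage order cannot change results.
#'
#' @param config a list (see \code{\link{pipeline_config}}).
#' @return Invisibly, a list of the in-memory results; files are written
#'   under \code{config$output_dir}.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stopifnot(is.list(cfg), !is.null(cfg$output_dir))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  logit <- function(...) {
    line <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), line))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  logit("pipeline start; betagrad %s; seed %d",
        as.character(utils::packageVersion("betagrad")), seed)

  # --- input ----------------------------------------------------------
  res <- list()
  input <- stage("input", {
    if (!is.null(cfg$input)) {
      list(table = read_specimen_table(cfg$input, schema = cfg$schema),
           truth = NULL)
    } else {
      gc <- cfg$synthetic
      if (is.null(gc)) gc <- nui_chua_default_config(seed = seed)
      if (is.null(gc$seed) || gc$seed != seed) gc$seed <- seed
      sim <- generate_gradient_community(gc)
      jsonlite::write_json(sim$truth, file.path(cfg$output_dir,
                                                "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      sim
    }
  })
  tab <- input$table
  res$truth <- input$truth
  hyp <- if (is.null(cfg$hypothesis)) hypotheses(tab)[1] else cfg$hypothesis
  if (!hyp %in% hypotheses(tab))
    stop("pipeline stage 'input' failed: hypothesis column 'species_", hyp,
         "' not present", call. = FALSE)
  if (isTRUE(cfg$exclude_dh) && "path" %in% names(tab)) {
    n0 <- nrow(tab)
    tab <- new_specimen_table(tab[tab$path != "DH", , drop = FALSE])
    logit("excluded DH path records: %d", n0 - nrow(tab))
  }
  res$table <- tab
  logit("input: %d specimens, hypothesis '%s'", nrow(tab), hyp)

  units <- if (is.null(cfg$units)) c("locality", "path", "biome") else
    cfg$units
  threshold <- if (is.null(cfg$biome_threshold)) 300 else cfg$biome_threshold
  n_boot <- if (is.null(cfg$n_boot)) 100 else cfg$n_boot

  # --- incidence + richness -------------------------------------------
  res$incidence <- stage("incidence", {
    out <- lapply(units, function(u)
      build_incidence(tab, hyp, u, threshold_m = threshold))
    names(out) <- units
    for (u in units)
      write_incidence(out[[u]], file.path(cfg$output_dir,
                                          paste0("incidence_", u, ".tsv")))
    out
  })
  res$richness <- stage("richness", {
    rows <- lapply(units, function(u) {
      rt <- richness_table(res$incidence[[u]], n_boot = n_boot,
                           seed = seed + 101L)
      cbind(partition = u, rt)
    })
    rt <- do.call(rbind, rows)
    utils::write.table(rt, file.path(cfg$output_dir, "richness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rt
  })

  # --- similarity + beta over paths -----------------------------------
  by_unit <- if ("path" %in% units) "path" else units[1]
  Xp <- res$incidence[[by_unit]]
  res$similarity <- stage("similarity", {
    if (ncol(Xp) >= 2) {
      sor <- similarity_matrix(Xp, "sorensen")
      jac <- similarity_matrix(Xp, "jaccard")
      comb <- sor; comb[upper.tri(comb)] <- jac[upper.tri(jac)]
      utils::write.table(round(comb, 3),
                         file.path(cfg$output_dir, "similarity.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      list(sorensen = sor, jaccard = jac)
    } else NULL
  })
  res$beta <- stage("beta", {
    if (ncol(Xp) >= 2) {
      bas <- baselga_multisite(Xp)
      car <- carvalho_multisite(Xp)
      df <- data.frame(
        family = c(bas$family, car$family),
        scope = c(bas$scope, car$scope),
        total = c(bas$total, car$total),
        turnover = c(bas$turnover, car$turnover),
        nestedness_or_richness = c(bas$nestedness_or_richness,
                                   car$nestedness_or_richness))
      utils::write.table(df, file.path(cfg$output_dir, "beta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      D <- 1 - res$similarity$sorensen
      diag(D) <- 0
      tree <- upgma(D)
      as_newick(tree, file.path(cfg$output_dir, "dendrogram.nwk"))
      list(baselga = bas, carvalho = car, dendrogram = tree)
    } else NULL
  })

  # --- ecotone ---------------------------------------------------------
  width <- if (is.null(cfg$bin_width)) 40 else cfg$bin_width
  res$ecotone <- stage("ecotone", {
    prof <- sliding_profile(slice_elevation(tab, width), hyp,
                            exclude_singletons =
                              isTRUE(cfg$exclude_singletons))
    utils::write.table(as.data.frame(prof),
                       file.path(cfg$output_dir, "ecotone_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    call <- detect_ecotone(prof)
    jsonlite::write_json(
      list(detected = call$detected, boundary = call$boundary,
           transition_interval = call$transition_interval,
           note = call$confidence_note),
      file.path(cfg$output_dir, "ecotone_call.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(profile = prof, call = call)
  })

  # --- hypothesis comparison ------------------------------------------
  res$comparison <- stage("comparison", {
    if (!is.null(cfg$reference_hypothesis) &&
        cfg$reference_hypothesis %in% hypotheses(tab)) {
      cmp <- compare_partitions(tab, cfg$reference_hypothesis, hyp)
      out <- list(reference = cmp$reference, test = cmp$test,
                  n_reference = cmp$n_reference, agree = cmp$agree,
                  split = cmp$split, merge = cmp$merge,
                  complex = cmp$complex,
                  match_percentage = match_percentage(cmp))
      jsonlite::write_json(out, file.path(cfg$output_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cmp
    } else NULL
  })

  logit("pipeline complete; outputs in %s", cfg$output_dir)
  writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  invisible(res)
}

#' Build a pipeline configuration
#'
#' @param input path to a specimen CSV/TSV, or \code{NULL} to simulate.
#' @param synthetic a \code{gradient_config} used when \code{input} is
#'   \code{NULL} (default: \code{nui_chua_default_config()}).
#' @param hypothesis species-hypothesis name (default: first available).
#' @param units unit definitions to analyse (default locality, path, biome).
#' @param biome_threshold biome boundary in metres (default 300).
#' @param bin_width elevation bin width for the ecotone stage (default 40).
#' @param n_boot rarefaction bootstrap replicates (default 100).
#' @param exclude_dh drop DH-path records (default TRUE).
#' @param exclude_singletons singleton policy for the ecotone profile.
#' @param reference_hypothesis reference partition for agreement scoring, or
#'   \code{NULL} to skip the comparison stage.
#' @param output_dir output directory.
#' @param seed root seed for all stochastic stages.
#' @param schema optional column mapping for \code{\link{read_specimen_table}}.
#' @return Config list for \code{\link{run_pipeline}}.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, hypothesis = NULL,
                            units = c("locality", "path", "biome"),
                            biome_threshold = 300, bin_width = 40,
                            n_boot = 100, exclude_dh = TRUE,
                            exclude_singletons = FALSE,
                            reference_hypothesis = NULL,
                            output_dir = tempfile("betagrad_run_"),
                            seed = 1L, schema = NULL) {
  list(input = input, synthetic = synthetic, hypothesis = hypothesis,
       units = units, biome_threshold = biome_threshold,
       bin_width = bin_width, n_boot = n_boot, exclude_dh = exclude_dh,
       exclude_singletons = exclude_singletons,
       reference_hypothesis = reference_hypothesis,
       output_dir = output_dir, seed = as.integer(seed), schema = schema)
}
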