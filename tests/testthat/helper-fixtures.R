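# Fixture builders and independent oracles shared across the test files.

# Minimal specimen table from parallel vectors; fills coordinates and ids.
make_table <- function(species, locality = "L1", path = substr(locality, 1, 2),
                       elevation = 100, latitude = 11.7, longitude = 109.2,
                       haplotype = NULL, hypothesis = "test") {
  n <- length(species)
  df <- data.frame(
    specimen_id = sprintf("X%04d", seq_len(n)),
    path = rep_len(path, n),
    locality = rep_len(locality, n),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    elevation_m = rep_len(elevation, n),
    stringsAsFactors = FALSE)
  df[[paste0("species_", hypothesis)]] <- species
  if (!is.null(haplotype)) df$haplotype <- rep_len(haplotype, n)
  betagrad:::new_specimen_table(df)
}

# Random 0/1 incidence matrix with no all-zero species row.
random_incidence <- function(n_species, n_units, p = 0.4) {
  repeat {
    X <- matrix(rbinom(n_species * n_units, 1, p), n_species, n_units,
                dimnames = list(sprintf("s%02d", seq_len(n_species)),
                                sprintf("u%02d", seq_len(n_units))))
    if (all(rowSums(X) > 0)) return(X)
  }
}

# Brute-force multiple-site Baselga sums, written directly from the
# definition with scalar loops (independent of the matrix-algebra path).
oracle_baselga_multisite <- function(X) {
  sets <- apply(X > 0, 2, function(col) rownames(X)[col], simplify = FALSE)
  n <- length(sets)
  smin <- smax <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bij <- length(setdiff(sets[[i]], sets[[j]]))
    bji <- length(setdiff(sets[[j]], sets[[i]]))
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  core <- sum(lengths(sets)) - length(unique(unlist(sets)))
  bsim <- smin / (core + smin)
  bsor <- (smin + smax) / (2 * core + smin + smax)
  c(total = bsor, turnover = bsim, nestedness = bsor - bsim)
}

# Monte-Carlo rarefaction oracle: mean richness over random t-unit subsets.
oracle_rarefaction <- function(X, t, n_rep = 2000) {
  m <- ncol(X)
  mean(replicate(n_rep, {
    sub <- X[, sample.int(m, t), drop = FALSE]
    sum(rowSums(sub) > 0)
  }))
}

# O(n^2) scan for the farthest locality pair.
oracle_max_distance <- function(df) {
  best <- c(NA, NA, -1)
  for (i in seq_len(nrow(df) - 1)) for (j in (i + 1):nrow(df)) {
    d <- great_circle_km(df$latitude[i], df$longitude[i],
                         df$latitude[j], df$longitude[j])
    if (d > best[3]) best <- c(i, j, d)
  }
  list(locality1 = df$locality[best[1]], locality2 = df$locality[best[2]],
       km = best[3])
}

# Random partition of n specimens into about k blocks.
random_partition <- function(n, k) sprintf("p%02d", sample.int(k, n, TRUE))
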