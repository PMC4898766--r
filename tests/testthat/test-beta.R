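test_that("baselga_pair matches hand-evaluated decompositions", {
  ident <- pair_counts(letters[1:5], letters[1:5])
  d0 <- baselga_pair(ident)
  expect_equal(c(d0$total, d0$turnover, d0$nestedness_or_richness),
               c(0, 0, 0))
  # strict nesting: all dissimilarity is nestedness-resultant
  nest <- list(a = 5, b = 0, c = 5)
  dn <- baselga_pair(nest)
  expect_equal(dn$turnover, 0)
  expect_equal(dn$total, 1 / 3)
  expect_equal(dn$nestedness_or_richness, 1 / 3)
  # the DD-NO reconstruction: a = 9, b = 14, c = 43
  d <- baselga_pair(list(a = 9, b = 14, c = 43))
  expect_equal(round(d$total, 3), 0.760)
  expect_equal(round(d$turnover, 3), 0.609)
  expect_equal(round(d$nestedness_or_richness, 3), 0.151)
  expect_equal(d$total, 1 - 0.240, tolerance = 1e-12)
  expect_error(baselga_pair(list(a = 0, b = 0, c = 0)), "empty")
})

test_that("carvalho_pair matches hand evaluation in both families", {
  d <- carvalho_pair(list(a = 9, b = 14, c = 43))
  expect_equal(round(d$total, 3), 0.864)
  expect_equal(round(d$turnover, 3), 0.424)
  expect_equal(round(d$nestedness_or_richness, 3), 0.439)
  # equal richness difference vanishes
  eq <- carvalho_pair(list(a = 3, b = 4, c = 4))
  expect_equal(eq$nestedness_or_richness, 0)
  ident <- carvalho_pair(pair_counts(letters[1:4], letters[1:4]))
  expect_equal(ident$total, 0)
  # Sorensen family uses the 2a+b+c denominator
  ds <- carvalho_pair(list(a = 9, b = 14, c = 43), family = "sorensen")
  expect_equal(ds$total, 57 / 75)
})

test_that("additivity is exact and families order consistently", {
  set.seed(81)
  n <- 2000
  a <- sample(0:30, n, TRUE); b <- sample(0:30, n, TRUE)
  cc <- sample(0:30, n, TRUE)
  keep <- (a + b + cc) > 0
  for (i in which(keep)[1:500]) {
    pc <- list(a = a[i], b = b[i], c = cc[i])
    bd <- baselga_pair(pc)
    cd <- carvalho_pair(pc)
    cs <- carvalho_pair(pc, "sorensen")
    expect_identical(bd$total, bd$turnover + bd$nestedness_or_richness)
    expect_identical(cd$total, cd$turnover + cd$nestedness_or_richness)
    expect_identical(cs$total, cs$turnover + cs$nestedness_or_richness)
    # Jaccard-family total >= Sorensen-family total
    expect_gte(cd$total, bd$total)
  }
})

test_that("turnover in random nested pairs is zero", {
  set.seed(91)
  for (i in 1:20) {
    inner <- sample(letters, sample(2:10, 1))
    outer <- union(inner, sample(letters, sample(1:10, 1)))
    d <- baselga_pair(pair_counts(inner, outer))
    expect_equal(d$turnover, 0)
  }
})

test_that("baselga_multisite reduces to the pair case and matches the oracle", {
  set.seed(101)
  # n = 2 reduction
  X2 <- random_incidence(10, 2)
  ms <- baselga_multisite(X2)
  pw <- baselga_pair(pair_counts(rownames(X2)[X2[, 1] > 0],
                                 rownames(X2)[X2[, 2] > 0]))
  expect_equal(ms$total, pw$total)
  expect_equal(ms$turnover, pw$turnover)
  # identical sites
  Xi <- matrix(1L, 5, 4)
  rownames(Xi) <- letters[1:5]
  expect_equal(baselga_multisite(Xi)$total, 0)
  # 3-site toy {AB, BC, CA}: every pair shares one species
  Xt <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  Xt[c("A", "B"), 1] <- 1L; Xt[c("B", "C"), 2] <- 1L; Xt[c("C", "A"), 3] <- 1L
  dt <- baselga_multisite(Xt)
  expect_equal(dt$total, 0.5)
  expect_equal(dt$turnover, 0.5)
  expect_equal(dt$nestedness_or_richness, 0)
  # brute-force oracle on random matrices up to 6 sites
  for (rep in 1:10) {
    X <- random_incidence(sample(6:14, 1), sample(3:6, 1))
    got <- baselga_multisite(X)
    want <- oracle_baselga_multisite(X)
    expect_equal(got$total, unname(want["total"]))
    expect_equal(got$turnover, unname(want["turnover"]))
    expect_equal(got$nestedness_or_richness, unname(want["nestedness"]))
  }
  expect_error(baselga_multisite(matrix(1, 3, 1)), "2 units")
})

test_that("carvalho_multisite averages pairwise components additively", {
  set.seed(111)
  X <- random_incidence(12, 4)
  d <- carvalho_multisite(X)
  expect_equal(d$total, d$turnover + d$nestedness_or_richness,
               tolerance = 1e-12)
  # mean-over-pairs definition, checked directly
  tots <- c()
  for (i in 1:3) for (j in (i + 1):4)
    tots <- c(tots, carvalho_pair(pair_counts(rownames(X)[X[, i] > 0],
                                              rownames(X)[X[, j] > 0]))$total)
  expect_equal(d$total, mean(tots))
})

test_that("turnover_fraction divides components", {
  d <- baselga_pair(list(a = 9, b = 14, c = 43))
  expect_equal(round(turnover_fraction(d), 3), 0.801)
  expect_equal(turnover_fraction(baselga_pair(list(a = 5, b = 0, c = 5))), 0)
  expect_equal(turnover_fraction(baselga_pair(list(a = 3, b = 4, c = 4))), 1)
  ident <- baselga_pair(pair_counts(letters[1:3], letters[1:3]))
  expect_error(turnover_fraction(ident), "undefined")
})

test_that("upgma clusters the printed path similarities as reported", {
  sim <- nui_chua_path_similarity()
  paths <- c("AH", "DD", "MN", "NO", "ST")
  D <- matrix(0, 5, 5, dimnames = list(paths, paths))
  for (k in seq_len(nrow(sim))) {
    D[sim$path1[k], sim$path2[k]] <- 1 - sim$sorensen[k]
    D[sim$path2[k], sim$path1[k]] <- 1 - sim$sorensen[k]
  }
  h <- upgma(D)
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("NO", "ST"))   # the two most similar transects
  expect_equal(h$height[1], 1 - 0.460)
})

test_that("upgma handles two leaves and reproduces ultrametric input", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  h2 <- upgma(D2)
  expect_equal(h2$height, 0.4)
  # an ultrametric matrix is reproduced exactly by cophenetic distances
  Du <- matrix(c(0, .2, .6, .6,
                 .2, 0, .6, .6,
                 .6, .6, 0, .3,
                 .6, .6, .3, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  hu <- upgma(Du)
  expect_equal(as.matrix(stats::cophenetic(hu))[letters[1:4], letters[1:4]],
               Du)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("upgma agrees with the stats::hclust average-linkage oracle", {
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    D <- as.matrix(stats::dist(matrix(stats::runif(n * 3), n)))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- stats::cophenetic(upgma(D))
    ref <- stats::cophenetic(stats::hclust(stats::as.dist(D),
                                           method = "average"))
    expect_equal(as.matrix(mine)[letters[1:n], letters[1:n]],
                 as.matrix(ref)[letters[1:n], letters[1:n]],
                 tolerance = 1e-12)
  }
})

test_that("newick export keeps leaves and ultrametric depths", {
  set.seed(131)
  D <- as.matrix(stats::dist(matrix(stats::runif(15), 5)))
  dimnames(D) <- list(paste0("t", 1:5), paste0("t", 1:5))
  h <- upgma(D)
  txt <- as_newick(h)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, paste0("t", 1:5))
  depths <- ape::node.depth.edgelength(phy)[1:5]
  expect_lt(max(depths) - min(depths), 1e-6)
  expect_equal(max(depths), max(h$height) / 2, tolerance = 1e-6)
})

test_that("distance_decay recovers an exactly linear relationship", {
  # three equatorial localities; compositions chosen so similarity is an
  # exact linear function of distance
  tab <- make_table(
    c("a", "b", "c", "d",  "c", "d", "e", "f",  "e", "f", "g", "h"),
    locality = rep(c("L1", "L2", "L3"), each = 4),
    path = "PP",
    latitude = 0,
    longitude = rep(c(0, 0.5, 1), each = 4),
    elevation = 10)
  dd <- distance_decay(tab, "test")
  d12 <- great_circle_km(0, 0, 0, 0.5)
  expect_equal(dd$fit$slope, -0.5 / d12, tolerance = 1e-9)
  expect_equal(dd$fit$intercept, 1, tolerance = 1e-9)

  # identical compositions everywhere: zero slope
  tab0 <- make_table(rep(c("a", "b"), 3),
                     locality = rep(c("L1", "L2", "L3"), each = 2),
                     path = "PP", latitude = 0,
                     longitude = rep(c(0, 0.5, 1), each = 2), elevation = 10)
  expect_equal(distance_decay(tab0, "test")$fit$slope, 0, tolerance = 1e-12)
})

test_that("synthetic gradient communities show negative distance decay", {
  for (s in 1:3) {
    sim <- generate_gradient_community(nui_chua_default_config(seed = 200 + s))
    dd <- distance_decay(sim$table, "true")
    expect_lt(dd$fit$slope, 0)
  }
})
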