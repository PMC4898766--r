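# Matrix with per-species unit counts {1,1,2,3,4} over m = 4 units:
# S_obs = 5, Q1 = 2, Q2 = 1.
fc_fixture <- function() {
  X <- matrix(0L, 5, 4, dimnames = list(paste0("s", 1:5), paste0("u", 1:4)))
  X[1, 1] <- 1L
  X[2, 2] <- 1L
  X[3, c(1, 2)] <- 1L
  X[4, 1:3] <- 1L
  X[5, 1:4] <- 1L
  X
}

test_that("incidence_frequencies tallies unit counts exactly", {
  fc <- incidence_frequencies(fc_fixture())
  expect_equal(fc$S_obs, 5L)
  expect_equal(fc$m, 4L)
  expect_equal(unname(fc$Q[1:4]), c(2L, 1L, 1L, 1L))
  expect_equal(fc$total_incidences, 11)

  # every species in every unit
  full <- matrix(1L, 3, 4)
  fc2 <- incidence_frequencies(full)
  expect_equal(unname(fc2$Q[1]), 0L)
  expect_equal(unname(fc2$Q[4]), 3L)

  # single unit: everything is a unique
  one <- matrix(1L, 6, 1)
  expect_equal(unname(incidence_frequencies(one)$Q[1]), 6L)

  expect_error(incidence_frequencies(matrix(0L, 0, 3)), "empty")
})

test_that("chao2 matches hand-evaluated classic and bias-corrected forms", {
  X <- fc_fixture()
  # classic: 5 + (3/4) * 4 / 2 = 6.5
  expect_equal(chao2(X, mode = "classic")$value, 6.5)
  # bias-corrected: 5 + (3/4) * 2 * 1 / (2 * 2) = 5.375
  expect_equal(chao2(X, mode = "bias_corrected")$value, 5.375)
  expect_gte(chao2(X)$sd, 0)

  # Q1 = 0: no unseen-species signal in any mode
  full <- matrix(1L, 4, 3)
  for (m in c("auto", "classic", "bias_corrected"))
    expect_equal(chao2(full, mode = m)$value, 4)

  expect_error(chao2(matrix(1L, 3, 1)), "2 sample-units")
})

test_that("chao2 auto mode switches on the incidence CV", {
  # low spread: counts {2,2,2,3} -> CV well below 0.5 -> bias-corrected
  Xlow <- matrix(0L, 4, 4)
  Xlow[1, 1:2] <- 1L; Xlow[2, 2:3] <- 1L; Xlow[3, 3:4] <- 1L; Xlow[4, 1:3] <- 1L
  auto_low <- chao2(Xlow, mode = "auto")
  expect_equal(auto_low$value, chao2(Xlow, mode = "bias_corrected")$value)
  expect_match(auto_low$mode_notes, "bias_corrected")

  # high spread: counts {1,1,1,1,8} over m = 8 -> CV > 0.5 -> classic
  Xhi <- matrix(0L, 5, 8)
  Xhi[1, 1] <- 1L; Xhi[2, 2] <- 1L; Xhi[3, 3] <- 1L; Xhi[4, 4] <- 1L
  Xhi[5, ] <- 1L
  auto_hi <- chao2(Xhi, mode = "auto")
  expect_match(auto_hi$mode_notes, "classic")
  expect_equal(auto_hi$value, chao2(Xhi, mode = "classic")$value)
})

test_that("chao2 and jackknives agree with vegan::specpool", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (rep in 1:8) {
    X <- random_incidence(12, 6)
    pool <- vegan::specpool(as.data.frame(t(X)))
    fc <- incidence_frequencies(X)
    expect_equal(jackknife(X, 1)$value, pool$jack1, tolerance = 1e-12)
    expect_equal(jackknife(X, 2)$value, pool$jack2, tolerance = 1e-12)
    if (fc$Q[2] > 0)  # vegan uses the classic form when Q2 > 0
      expect_equal(chao2(fc, mode = "classic")$value, pool$chao,
                   tolerance = 1e-12)
  }
})

test_that("ICE matches the hand-evaluated Lee-Chao formula", {
  # infrequent counts {1,1,2} over m_inf = 3 units, no frequent species:
  # N_inf = 4, C_ice = 0.5, gamma2 = 0.125, ICE = 6 + 4*0.125 = 6.5
  X <- matrix(0L, 3, 3)
  X[1, 1] <- 1L; X[2, 2] <- 1L; X[3, c(1, 3)] <- 1L
  expect_equal(ice(X)$value, 6.5)

  # all species frequent: ICE = S_obs
  Xf <- matrix(1L, 4, 3)
  expect_equal(ice(Xf, frequency_cutoff = 2)$value, 4)

  # all infrequent incidences unique: Chao2-bc fallback
  Xu <- diag(1L, 4)
  est <- ice(Xu)
  expect_match(est$mode_notes, "fallback")
  expect_equal(est$value, chao2(Xu, mode = "bias_corrected")$value)
})

test_that("jackknife matches hand evaluation and degenerate cases", {
  X <- fc_fixture()
  expect_equal(jackknife(X, 1)$value, 5 + 2 * 3 / 4)            # 6.5
  expect_equal(jackknife(X, 2)$value, 5 + 2 * 5 / 4 - 1 * 4 / 12,
               tolerance = 1e-12)                               # 7.1667
  full <- matrix(1L, 4, 4)
  expect_equal(jackknife(full, 1)$value, 4)
  expect_equal(jackknife(full, 2)$value, 4)
  expect_error(jackknife(matrix(1L, 2, 2), 2), "m >= 3")
})

test_that("rarefaction endpoints and degenerate cases are exact", {
  X <- fc_fixture()
  rc <- rarefy_extrapolate(X, target_factor = 2, n_boot = 0)
  expect_equal(rc$curve$S[4], 5)                      # t = m -> S_obs
  expect_equal(rc$curve$S[1], mean(colSums(X)))       # t = 1 -> mean richness
  # Q1 = 0 -> flat extrapolation
  full <- matrix(1L, 4, 3)
  rcf <- rarefy_extrapolate(full, target_factor = 3, n_boot = 0)
  expect_true(all(rcf$curve$S[rcf$curve$t >= 3] == 4))
  expect_error(rarefy_extrapolate(matrix(1L, 3, 1)), "2 sample-units")
})

test_that("interpolation matches a Monte-Carlo subsampling oracle", {
  set.seed(31)
  X <- random_incidence(15, 8)
  rc <- rarefy_extrapolate(X, target_factor = 1, n_boot = 0)
  for (t in c(2, 4, 6)) {
    mc <- oracle_rarefaction(X, t, n_rep = 3000)
    expect_equal(rc$curve$S[t], mc, tolerance = 0.05)
  }
})

test_that("interpolated curve is monotone and concave", {
  set.seed(41)
  for (rep in 1:6) {
    X <- random_incidence(sample(8:20, 1), sample(4:9, 1))
    S <- rarefy_extrapolate(X, target_factor = 1, n_boot = 0)$curve$S
    expect_true(all(diff(S) > -1e-9))
    if (length(S) > 2) expect_true(all(diff(diff(S)) < 1e-9))
  }
})

test_that("estimators exceed S_obs when uniques exist and ignore labels", {
  set.seed(51)
  for (rep in 1:10) {
    X <- random_incidence(sample(8:16, 1), sample(4:8, 1), p = 0.25)
    fc <- incidence_frequencies(X)
    if (fc$Q[1] == 0) next
    expect_gte(chao2(X)$value, fc$S_obs)
    expect_gte(chao2(X, "classic")$value, fc$S_obs)
    expect_gte(jackknife(X, 1)$value, fc$S_obs)
    expect_gte(ice(X)$value, fc$S_obs)
    # invariance to permutation of species and units
    Xp <- X[sample(nrow(X)), sample(ncol(X))]
    expect_equal(chao2(Xp)$value, chao2(X)$value)
    expect_equal(ice(Xp)$value, ice(X)$value)
    expect_equal(jackknife(Xp, 2)$value, jackknife(X, 2)$value)
  }
})

test_that("estimators recover truth on completely sampled communities", {
  cfg <- gradient_config(nui_chua_localities(), visits = 6L,
                         baseline_detection = 1, abundance_sdlog = 0,
                         seed = 8)
  sim <- generate_gradient_community(cfg)
  X <- build_incidence(sim$table, "true", "locality")
  tr <- sim$truth$species
  loc <- cfg$localities
  S_reachable <- sum(vapply(seq_len(nrow(tr)), function(i)
    any(loc$elevation_m >= tr$range_low[i] &
          loc$elevation_m < tr$range_high[i]), logical(1)))
  expect_equal(incidence_frequencies(X)$S_obs, S_reachable)
  # with saturating detection there is little unseen-species signal left
  expect_lt(chao2(X)$value, S_reachable * 1.25)
})

test_that("richness_table bundles the Table-5 battery", {
  X <- random_incidence(20, 8)
  rt <- richness_table(X, n_boot = 20, seed = 1)
  expect_setequal(sub("^Chao2-.*", "Chao2", rt$estimator),
                  c("Rarefaction3x", "ICE", "Chao2", "Jack1", "Jack2"))
  expect_true(all(rt$value >= incidence_frequencies(X)$S_obs - 1e-9))
})
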