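test_that("detection correction scales counts to densities", {
  expect_equal(corrected_density(10, 20, 0.5), 1)
  expect_equal(corrected_density(0, 12, 0.3), 0)
  expect_error(corrected_density(10, 20, 0), "p_detect")
  expect_error(corrected_density(10, -1, 0.5), "area")
  # homogeneity in the count
  expect_equal(corrected_density(14, 33, 0.4),
               2 * corrected_density(7, 33, 0.4))
})

test_that("distance weighting follows the exponential decay kernel", {
  expect_equal(distance_weighted_density(2, 5, 0.1), 2)
  # two sections 10 m apart, unit density only in section 1
  w <- distance_weighted_density(c(1, 0), c(5, 15), 0.1)
  expect_equal(w, c(1, exp(-1)))
  # lambda = 0 pools everything
  D <- c(0.5, 1.2, 0.3)
  expect_equal(distance_weighted_density(D, c(5, 15, 25), 0),
               rep(sum(D), 3))
  expect_error(distance_weighted_density(c(-1, 0), c(5, 15), 0.1),
               "negative")
})

test_that("distance weighting matches a brute-force double loop", {
  set.seed(42)
  mids <- section_midpoint(1:43, 10)
  for (rep in 1:5) {
    D <- runif(43, 0, 2)
    fast <- distance_weighted_density(D, mids, 0.1)
    slow <- vapply(1:43, function(s)
      sum(D * exp(-0.1 * abs(mids[s] - mids))), 0)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("distance weighting is linear in density and monotone in lambda", {
  set.seed(7)
  mids <- section_midpoint(1:20, 10)
  D1 <- runif(20); D2 <- runif(20)
  f <- function(D, l = 0.1) distance_weighted_density(D, mids, l)
  expect_equal(f(2 * D1 + 3 * D2), 2 * f(D1) + 3 * f(D2))
  lams <- c(0, 0.05, 0.1, 0.5, 2)
  vals <- sapply(lams, function(l) f(D1, l))
  expect_true(all(diff(t(vals)) <= 1e-12))  # each entry non-increasing
})

test_that("z-scoring uses the sample sd and stores constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1))
  expect_equal(z$mean, 2)
  expect_equal(z$sd, 1)
  set.seed(3)
  v <- rnorm(50, 10, 4)
  z <- zscore(v)
  expect_lt(abs(mean(z$values)), 1e-12)
  expect_equal(sd(z$values), 1)
  expect_error(zscore(c(5, 5, 5)), "constant")
})

test_that("ratio normalization is per-occasion with a zero fallback", {
  expect_equal(ratio_normalize(c(2, 4), c(1, 1)), c(2 / 3, 4 / 3))
  expect_equal(ratio_normalize(rep(3.7, 5), rep(2, 5)), rep(1, 5))
  expect_warning(out <- ratio_normalize(c(0, 0, 2, 4), c(1, 1, 2, 2)),
                 "zero cross-sectional mean")
  expect_equal(out, c(0, 0, 2 / 3, 4 / 3))
  # per-occasion mean of the output is 1
  set.seed(9)
  v <- rlnorm(40); occ <- rep(1:4, each = 10)
  out <- ratio_normalize(v, occ)
  expect_equal(as.vector(tapply(out, occ, mean)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("density surfaces and covariate assembly are consistent", {
  reach <- generate_reach(n_sections = 8, n_occasions = 4, seed = 2)
  sim <- simulate_individuals(study_truths(scale = 0.3)[1:2], reach,
                              seed = 2)
  ds <- emit_dataset(sim)
  species_set <- c("bluehead_chub", "creek_chub")
  suppressWarnings(
    surf <- density_surfaces(ds$captures, ds$habitat, ds$sections,
                             species_set))
  expect_true(all(surf$weighted_density >= surf$density - 1e-12))
  expect_true(all(surf$density >= 0))

  reps <- build_replicates(ds$captures, ds$occasions)
  reps <- reps[reps$species == "creek_chub", ]
  cov <- assemble_covariates(reps, surf, ds$habitat, ds$occasions,
                             species_set)
  # z-scored columns: mean 0, sample sd 1
  for (nm in c("body_size", "density_bluehead_chub", "density_creek_chub",
               "julian_day")) {
    expect_lt(abs(mean(cov$X[, nm])), 1e-10)
    expect_equal(sd(cov$X[, nm]), 1, tolerance = 1e-10)
  }
  expect_equal(cov$predictors,
               c("body_size", "density_bluehead_chub",
                 "density_creek_chub", "julian_day", "hra", "velocity"))
  # detection correction halves of p double the density
  det <- expand.grid(species = species_set, occasion = 1:4,
                     stringsAsFactors = FALSE)
  det$p_detect <- 0.5
  surf2 <- density_surfaces(ds$captures, ds$habitat, ds$sections,
                            species_set, detection = det)
  expect_equal(surf2$density, 2 * surf$density)
})

test_that("two body sizes standardize to +/- 1/sqrt(2)", {
  z <- zscore(c(80, 100))
  expect_equal(z$values, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("uniform HRA ratio-normalizes to exactly 1", {
  occ <- std_occasions(3)
  tab <- cap_rows(c("A1", "A2", "A3", "A4"), "creek_chub", c(1, 1, 2, 2),
                  c(2, 2, 4, 5), c(80, 100, 90, 110))
  reps <- build_replicates(tab, occ)
  hab <- expand.grid(occasion = 1:3, section = 1:5)
  hab$area_m2 <- 30; hab$hra_m2 <- 0.5; hab$velocity_ms <- 0.06
  suppressWarnings(
    surf <- density_surfaces(tab, hab, make_sections(5), "creek_chub"))
  cov <- assemble_covariates(reps, surf, hab, occ, "creek_chub")
  expect_equal(unname(cov$X[, "hra"]), rep(1, nrow(reps)))
  expect_equal(unname(cov$X[, "velocity"]), rep(1, nrow(reps)))
})

test_that("missing cells and constant density columns error clearly", {
  occ <- std_occasions(3)
  tab <- cap_rows(c("A1", "A2"), "creek_chub", c(1, 2), c(2, 3),
                  c(80, 100))
  reps <- build_replicates(tab, occ)
  hab <- expand.grid(occasion = 1:3, section = 1:5)
  hab$area_m2 <- 30; hab$hra_m2 <- 0.5; hab$velocity_ms <- 0.06
  # all-zero surface -> constant z-score column surfaces as an error
  surf <- expand.grid(occasion = 1:3, section = 1:5)
  surf$species <- "creek_chub"; surf$weighted_density <- 0
  expect_error(assemble_covariates(reps, surf, hab, occ, "creek_chub"),
               "density_creek_chub")
  # missing habitat cell is named
  expect_error(assemble_covariates(
    reps, surf, hab[hab$section != 2, ], occ, "creek_chub"),
    "missing cell")
})
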