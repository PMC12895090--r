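test_that("the default reach matches the study geometry and habitat scale", {
  reach <- generate_reach(seed = 3)
  expect_equal(nrow(reach$sections), 43)
  expect_equal(reach$L, 430)
  expect_equal(reach$sections$midpoint_m, seq(5, 425, by = 10))
  expect_equal(nrow(reach$occasions), 15)
  expect_equal(reach$occasions$interval_to_next[1], 93)
  # determinism
  expect_identical(generate_reach(seed = 3), reach)
  expect_false(identical(generate_reach(seed = 4)$habitat, reach$habitat))
})

test_that("habitat draws hit the target reach-wide moments", {
  # ~10^4 cells
  reach <- generate_reach(n_sections = 100, n_occasions = 100, seed = 8)
  expect_equal(mean(reach$habitat$hra_m2), 0.45, tolerance = 0.1)
  expect_equal(mean(reach$habitat$velocity_ms), 0.06, tolerance = 0.1)
  expect_equal(mean(reach$habitat$area_m2), 32.51, tolerance = 0.05)
  expect_true(all(reach$habitat$hra_m2 >= 0))
})

# total planted consecutive-occasion recapture events across species
planted_recaptures_total <- function(sim) {
  sum(emit_dataset(sim)$planted$consecutive_recaptures)
}

test_that("a degenerate kernel freezes individuals in place", {
  reach <- generate_reach(n_sections = 10, n_occasions = 5, seed = 1)
  tr <- species_truth("creek_chub", n_init = 40, beta0 = -30,
                      beta = c(body_size = 0), survival = 1,
                      p_capture = 1)
  sim <- simulate_individuals(tr, reach, seed = 2)
  # positions constant across occasions
  pos_by_id <- split(sim$trajectories$pos, sim$trajectories$id)
  expect_true(all(vapply(pos_by_id, function(p) diff(range(p)) < 1e-6,
                         TRUE)))
  # perfect observation: every individual captured at every occasion, in
  # its own section each time
  caps <- sim$captures
  expect_equal(nrow(caps), 40 * 5)
  sec_by_id <- split(caps$section, caps$tag_id)
  expect_true(all(vapply(sec_by_id, function(s) length(unique(s)) == 1,
                         TRUE)))
  # planted consecutive recaptures: every individual on every interval
  expect_equal(planted_recaptures_total(sim), 40 * 4)
})

test_that("emitted datasets round-trip through the io layer", {
  reach <- generate_reach(n_sections = 12, n_occasions = 6, seed = 5)
  sim <- simulate_individuals(study_truths(scale = 0.25)[1:2], reach,
                              seed = 5)
  dir <- withr::local_tempdir()
  ds <- emit_dataset(sim, dir)
  back <- read_captures(file.path(dir, "captures.csv"),
                        c("creek_chub", "bluehead_chub"),
                        n_occasions = 6, n_sections = 12)
  expect_equal(nrow(back), nrow(ds$captures))
  occ <- read_occasions(file.path(dir, "occasions.csv"))
  expect_equal(occ$interval_to_next, ds$occasions$interval_to_next)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$creek_chub$phi, ds$truth$creek_chub$phi)

  # count identity: Y = 1 replicates equal the planted consecutive
  # recapture events
  reps <- build_replicates(back, occ, section_length = 10)
  expect_equal(sum(reps$y == 1), sum(ds$planted$consecutive_recaptures))
  tal <- replicate_tallies(reps, back)
  expect_equal(sum(tal$replicate_recaptures),
               sum(ds$planted$consecutive_recaptures))
  expect_true(all(tal$unique_recaptured <= tal$replicate_recaptures))
  # every start location is a section midpoint
  expect_equal(reps$x0, section_midpoint(reps$section, 10))
})

test_that("study-scale scenario reproduces the abundance ranking", {
  reach <- generate_reach(seed = 10)
  sim <- simulate_individuals(study_truths(scale = 0.5), reach, seed = 10)
  ds <- emit_dataset(sim)
  n <- table(ds$captures$species)
  expect_gt(n[["creek_chub"]], n[["bluehead_chub"]])
  expect_gt(n[["creek_chub"]], n[["green_sunfish"]])
  expect_gt(n[["bluehead_chub"]], n[["redbreast_sunfish"]])
  expect_gt(n[["green_sunfish"]], n[["redbreast_sunfish"]])
  # tagging threshold respected
  expect_true(all(ds$captures$total_length_mm >= 60))
})

test_that("model-exact replicates have the stated observation structure", {
  # with near-certain recapture and no emigration, Y = 1 throughout
  gen <- simulate_replicates(500, beta0 = -20, beta = c(body_size = 0),
                             phi = 1 - 1e-12, seed = 2)
  expect_equal(mean(gen$replicates$y), 1)
  expect_true(all(abs(gen$replicates$x1 - gen$replicates$x0) < 1e-4))

  # stronger size effect raises the size-|displacement| correlation
  weak <- simulate_replicates(4000, beta = c(body_size = 0), seed = 3)
  strong <- simulate_replicates(4000, beta = c(body_size = 0.8), seed = 3)
  cor_of <- function(g) {
    ok <- g$replicates$y == 1
    cor(g$X[ok, "body_size"],
        abs(g$replicates$x1[ok] - g$replicates$x0[ok]),
        method = "spearman")
  }
  expect_gt(cor_of(strong), cor_of(weak) + 0.2)
})

test_that("recovery experiment scores coverage per parameter", {
  out <- recovery_experiment(
    n_reps = 1, n_replicates = 120,
    sampler = sampler_config(n_iter = 800, burn_in = 300, thin = 2,
                             n_chains = 2), seed = 7)
  expect_equal(nrow(out), 3)  # one row per parameter
  expect_setequal(out$parameter, c("beta0", "beta_body_size", "phi"))
  expect_true(all(is.finite(out$median_error)))
  sm <- recovery_summary(out)
  expect_equal(nrow(sm), 3)
  expect_true(all(sm$coverage %in% c(0, 1)))
})

test_that("a huge low-noise dataset concentrates the posterior on truth", {
  out <- recovery_experiment(
    n_reps = 1, n_replicates = 1500, phi = 0.8,
    sampler = sampler_config(n_iter = 2500, burn_in = 1000, thin = 3,
                             n_chains = 2), seed = 11)
  b0 <- out[out$parameter == "beta0", ]
  expect_lt(abs(b0$median_error), 0.1)
})
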