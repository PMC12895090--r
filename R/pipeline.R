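#' Load a dataset directory
#'
#' Reads the three pipeline tables (captures, habitat, occasions) written
#' by [emit_dataset()] or assembled from field data in the same layout.
#'
#' @param dir directory containing `captures.csv`, `habitat.csv`,
#'   `occasions.csv`.
#' @param species_set target species.
#' @param n_sections,section_length reach geometry.
#' @return list with `captures`, `habitat`, `occasions`, `sections`.
#' @export
load_dataset <- function(dir, species_set, n_sections = 43,
                         section_length = 10) {
  occasions <- read_occasions(file.path(dir, "occasions.csv"))
  captures <- read_captures(file.path(dir, "captures.csv"), species_set,
                            n_occasions = nrow(occasions),
                            n_sections = n_sections)
  list(captures = captures,
       habitat = read_habitat(file.path(dir, "habitat.csv")),
       occasions = occasions,
       sections = make_sections(n_sections, section_length))
}

#' Fit the dispersal-observation model for one species
#'
#' The full per-species chain: build movement replicates from the capture
#' histories, compute detection-corrected distance-weighted density
#' surfaces for all target species, assemble the standardized covariate
#' matrix, sample the posterior, and summarize coefficients, convergence
#' and predicted movement bands over the body-size gradient.
#'
#' @param data list with `captures`, `habitat`, `occasions`, `sections`
#'   (see [load_dataset()] or [emit_dataset()]).
#' @param species species to fit.
#' @param species_set species whose weighted densities enter as
#'   predictors; defaults to all species in the capture table.
#' @param detection optional detection-probability table (`species`,
#'   `occasion`, `p_detect`).
#' @param cfg [model_config()] object.
#' @param sampler [sampler_config()] object.
#' @param mode sampler mode.
#' @param lambda_ density distance-weighting decay rate (1/m).
#' @param outdir optional directory for the report files and draws.
#' @return `dom_report` with the draws attached as attribute `"draws"`.
#' @export
fit_species <- function(data, species, species_set = NULL,
                        detection = NULL, cfg = model_config(),
                        sampler = sampler_config(),
                        mode = "marginalized", lambda_ = 0.1,
                        outdir = NULL) {
  if (is.null(species_set))
    species_set <- sort(unique(data$captures$species))
  if (!species %in% data$captures$species)
    stop("no captures for species '", species, "'")
  replicates <- build_replicates(data$captures, data$occasions,
                                 section_length = data$sections$length_m[1])
  reps_sp <- replicates[replicates$species == species, , drop = FALSE]
  if (nrow(reps_sp) == 0)
    stop("zero movement replicates for species '", species, "'")
  surfaces <- density_surfaces(data$captures, data$habitat, data$sections,
                               species_set, detection = detection,
                               lambda_ = lambda_)
  cov <- assemble_covariates(reps_sp, surfaces, data$habitat,
                             data$occasions, species_set)
  dat <- dom_data(reps_sp, cov$X)
  draws <- sample_posterior(dat, cfg, sampler, mode = mode)
  sm <- summarize_coefficients(draws)
  conv <- check_convergence(draws)
  bands <- movement_band(draws,
                         data.frame(body_size = seq(-2, 2, by = 1)),
                         eta_ref = mean(data$occasions$interval_to_next,
                                        na.rm = TRUE))
  report <- species_report(species, sm, conv, bands)
  report$n_replicates <- nrow(reps_sp)
  report$scaling <- cov$scaling
  if (!is.null(outdir)) {
    write_report(report, outdir)
    write_draws(draws, file.path(outdir, paste0(species, "_draws.csv")))
  }
  attr(report, "draws") <- draws
  report
}

#' Fit every species and aggregate
#'
#' One model per species (no pooling), then a coefficient matrix across
#' species in the style of a multi-species posterior summary figure:
#' species x parameter rows of median, credible interval and posterior
#' probability. A species whose fit errors is recorded and does not stop
#' the others.
#'
#' @inheritParams fit_species
#' @param species_set species to fit (and whose densities are predictors).
#' @return list with `reports` (per species), `aggregate` (data.frame),
#'   `failures` (named character vector of error messages).
#' @export
run_all <- function(data, species_set = NULL, detection = NULL,
                    cfg = model_config(), sampler = sampler_config(),
                    mode = "marginalized", lambda_ = 0.1, outdir = NULL) {
  if (is.null(species_set))
    species_set <- sort(unique(data$captures$species))
  if (length(species_set) == 0) stop("empty species list")
  reports <- list()
  failures <- character(0)
  for (sp in species_set) {
    res <- tryCatch(
      fit_species(data, sp, species_set = species_set,
                  detection = detection, cfg = cfg, sampler = sampler,
                  mode = mode, lambda_ = lambda_, outdir = outdir),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[sp] <- conditionMessage(res)
    } else {
      reports[[sp]] <- res
    }
  }
  agg <- do.call(rbind, lapply(names(reports), function(sp) {
    cbind(species = sp, reports[[sp]]$coefficients)
  }))
  if (!is.null(outdir) && !is.null(agg)) {
    write.csv(agg, file.path(outdir, "coefficients_all_species.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(reports = reports, aggregate = agg, failures = failures)
}
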