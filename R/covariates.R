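#' Detection-corrected fish density
#'
#' Raw section counts under-represent true density because a single
#' electrofishing pass misses fish; dividing by a (season-specific)
#' detection probability corrects the count before converting to density
#' per square meter.
#'
#' @param count non-negative fish count in the section.
#' @param area_m2 wetted section area in square meters (> 0).
#' @param p_detect detection probability in (0, 1].
#' @return individuals per square meter.
#' @export
corrected_density <- function(count, area_m2, p_detect) {
  if (any(p_detect <= 0) || any(p_detect > 1))
    stop("p_detect must be in (0, 1]")
  if (any(area_m2 <= 0)) stop("area_m2 must be positive")
  if (any(count < 0)) stop("negative count")
  count / (p_detect * area_m2)
}

#' Distance-weighted density surface
#'
#' Convolves section densities with an exponential decay kernel so that
#' neighbours contribute in proportion to exp(-lambda * distance) between
#' section midpoints; the section's own density enters with weight 1. With
#' the study's lambda = 0.1 per meter, influence is strongest within about
#' 10 m but never truncated.
#'
#' @param D non-negative density vector over sections.
#' @param midpoints section midpoints in meters, same length as `D`.
#' @param lambda_ decay rate (1/m), >= 0.
#' @return weighted density vector, same length as `D`.
#' @export
distance_weighted_density <- function(D, midpoints, lambda_ = 0.1) {
  if (length(D) != length(midpoints))
    stop("D and midpoints must have the same length")
  if (any(D < 0)) stop("negative density")
  if (lambda_ < 0) stop("lambda must be >= 0")
  W <- exp(-lambda_ * abs(outer(midpoints, midpoints, "-")))
  as.vector(W %*% D)
}

#' Z-score standardization with stored constants
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return list with `values` (standardized), `mean`, `sd` (sample, n-1).
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  list(values = (values - m) / s, mean = m, sd = s)
}

#' Per-occasion ratio normalization
#'
#' Divides habitat values by their cross-sectional mean computed per
#' occasion, removing seasonal differences in level so that only spatial
#' contrast within an occasion remains; the per-occasion mean of the output
#' is 1. An occasion whose values are all zero is returned as zeros with a
#' warning rather than an error.
#'
#' @param values numeric vector.
#' @param occasion_ids occasion index per value.
#' @return normalized vector.
#' @export
ratio_normalize <- function(values, occasion_ids) {
  stopifnot(length(values) == length(occasion_ids))
  out <- numeric(length(values))
  for (occ in unique(occasion_ids)) {
    idx <- occasion_ids == occ
    m <- mean(values[idx])
    if (m == 0) {
      warning("ratio_normalize: occasion ", occ,
              " has zero cross-sectional mean; returning zeros")
      out[idx] <- 0
    } else {
      out[idx] <- values[idx] / m
    }
  }
  out
}

#' Species density surfaces from a capture table
#'
#' Counts all captured individuals of each species per occasion and
#' section (not only tagged fish), corrects for detection, converts to
#' density per square meter, and applies distance weighting.
#'
#' @param captures capture data.frame.
#' @param habitat habitat table (`occasion`, `section`, `area_m2`, ...).
#' @param sections section table from [make_sections()].
#' @param species_set species to build surfaces for.
#' @param detection optional data.frame `species`, `occasion`, `p_detect`;
#'   when omitted all probabilities default to 1 (raw densities) with a
#'   warning.
#' @param lambda_ decay rate for distance weighting (1/m).
#' @return data.frame with columns `species`, `occasion`, `section`,
#'   `raw_count`, `density`, `weighted_density`.
#' @export
density_surfaces <- function(captures, habitat, sections, species_set,
                             detection = NULL, lambda_ = 0.1) {
  if (is.null(detection)) {
    warning("no detection table supplied; using p_detect = 1 (raw densities)")
    detection <- expand.grid(species = species_set,
                             occasion = sort(unique(habitat$occasion)),
                             stringsAsFactors = FALSE)
    detection$p_detect <- 1
  }
  occ_ids <- sort(unique(habitat$occasion))
  out <- list()
  for (sp in species_set) {
    for (occ in occ_ids) {
      hab <- habitat[habitat$occasion == occ, , drop = FALSE]
      hab <- hab[match(sections$section, hab$section), , drop = FALSE]
      if (anyNA(hab$area_m2))
        stop("habitat table missing occasion ", occ, " x section cell")
      cap <- captures[captures$species == sp & captures$occasion == occ, ]
      counts <- tabulate(cap$section, nbins = nrow(sections))
      p <- detection$p_detect[detection$species == sp &
                                detection$occasion == occ]
      if (length(p) != 1)
        stop("detection table missing (", sp, ", occasion ", occ, ")")
      dens <- corrected_density(counts, hab$area_m2, p)
      out[[length(out) + 1]] <- data.frame(
        species = sp, occasion = occ, section = sections$section,
        raw_count = counts, density = dens,
        weighted_density = distance_weighted_density(
          dens, sections$midpoint_m, lambda_)
      )
    }
  }
  do.call(rbind, out)
}

#' Assemble the standardized covariate matrix for one species' model
#'
#' Looks up each replicate's covariates at its capture occasion and
#' section: body size, the four species' distance-weighted densities,
#' Julian day, habitat refuge area (HRA) and current velocity. Body size,
#' densities and Julian day are z-scored over the replicates entering this
#' fit; HRA and velocity are ratio-normalized by their per-occasion
#' cross-sectional means over the whole habitat table (a reach property,
#' not a replicate property). Standardization constants are attached for
#' later prediction on new covariate values.
#'
#' @param replicates replicate table for one species.
#' @param surfaces output of [density_surfaces()] (all species).
#' @param habitat habitat table.
#' @param occasions occasion table.
#' @param species_set species whose weighted densities enter as predictors.
#' @return list with `X` (numeric matrix, one column per predictor),
#'   `scaling` (per-column mean/sd or "ratio"), and `predictors`.
#' @export
assemble_covariates <- function(replicates, surfaces, habitat, occasions,
                                species_set) {
  n <- nrow(replicates)
  if (n == 0) stop("no replicates to assemble covariates for")
  dens_cols <- lapply(species_set, function(sp) {
    surf <- surfaces[surfaces$species == sp, , drop = FALSE]
    idx <- match(paste(replicates$occasion, replicates$section),
                 paste(surf$occasion, surf$section))
    if (anyNA(idx))
      stop("density surface missing cell (occasion ",
           replicates$occasion[which(is.na(idx))[1]], ", section ",
           replicates$section[which(is.na(idx))[1]], ") for ", sp)
    surf$weighted_density[idx]
  })
  names(dens_cols) <- paste0("density_", species_set)

  hab_norm <- habitat
  hab_norm$hra_norm <- ratio_normalize(habitat$hra_m2, habitat$occasion)
  hab_norm$vel_norm <- ratio_normalize(habitat$velocity_ms, habitat$occasion)
  hidx <- match(paste(replicates$occasion, replicates$section),
                paste(habitat$occasion, habitat$section))
  if (anyNA(hidx))
    stop("habitat table missing cell (occasion ",
         replicates$occasion[which(is.na(hidx))[1]], ", section ",
         replicates$section[which(is.na(hidx))[1]], ")")

  raw <- c(list(body_size = replicates$total_length_mm),
           dens_cols,
           list(julian_day =
                  as.numeric(occasions$julian_day[replicates$occasion])))
  scaling <- list()
  X <- matrix(NA_real_, n, 0)
  for (nm in names(raw)) {
    z <- tryCatch(zscore(raw[[nm]]),
                  error = function(e)
                    stop("covariate '", nm, "': ", conditionMessage(e)))
    X <- cbind(X, z$values)
    scaling[[nm]] <- list(type = "zscore", mean = z$mean, sd = z$sd)
  }
  X <- cbind(X, hab_norm$hra_norm[hidx], hab_norm$vel_norm[hidx])
  scaling$hra <- list(type = "ratio")
  scaling$velocity <- list(type = "ratio")
  colnames(X) <- c(names(raw), "hra", "velocity")
  list(X = X, scaling = scaling, predictors = colnames(X))
}
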