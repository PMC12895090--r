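#' Sampling occasions from survey dates
#'
#' Builds the occasion table used throughout the pipeline: occasion index,
#' calendar date, day-of-year, and the interval in days to the next
#' occasion (the basis of the time offset eta). The final occasion has no
#' following interval and gets `NA`.
#'
#' @param dates vector of survey dates (`Date` or ISO-8601 strings),
#'   strictly increasing.
#' @return data.frame with columns `occasion`, `date`, `julian_day`,
#'   `interval_to_next`.
#' @export
make_occasions <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable occasion date")
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("occasion dates must be strictly increasing")
  }
  n <- length(dates)
  data.frame(
    occasion = seq_len(n),
    date = dates,
    julian_day = as.integer(format(dates, "%j")),
    interval_to_next = c(as.numeric(diff(dates)), NA_real_)
  )
}

#' @rdname make_occasions
#' @param path CSV file with columns `occasion`, `date` (ISO 8601).
#' @export
read_occasions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("occasion", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occasions table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$occasion), , drop = FALSE]
  if (!identical(as.integer(df$occasion), seq_len(nrow(df)))) {
    stop("occasion indices must be 1..T without gaps")
  }
  make_occasions(df$date)
}

#' Section midpoint in meters from the downstream end
#'
#' Sections are half-open 10-m (by default) intervals anchored at the
#' downstream end of the reach; fish locations are the midpoints of their
#' capture sections, so section s sits at `length * (s - 1) + length / 2`.
#'
#' @param section_index integer section index (1-based, increasing upstream).
#' @param section_length section length in meters (default 10).
#' @param n_sections optional total section count; indices above it error.
#' @return midpoint in meters.
#' @export
section_midpoint <- function(section_index, section_length = 10,
                             n_sections = NULL) {
  if (any(section_index < 1))
    stop("section index must be >= 1")
  if (!is.null(n_sections) && any(section_index > n_sections))
    stop("section index exceeds number of sections (", n_sections, ")")
  section_length * (section_index - 1) + section_length / 2
}

#' Section table for a uniform reach
#'
#' @param n_sections number of contiguous sections (43 in the study reach).
#' @param section_length section length in meters.
#' @return data.frame with `section`, `length_m`, `midpoint_m`; the reach
#'   length `L = n_sections * section_length` is attached as attribute `L`.
#' @export
make_sections <- function(n_sections = 43, section_length = 10) {
  stopifnot(n_sections >= 1, section_length > 0)
  out <- data.frame(
    section = seq_len(n_sections),
    length_m = section_length,
    midpoint_m = section_midpoint(seq_len(n_sections), section_length)
  )
  attr(out, "L") <- n_sections * section_length
  out
}

#' Read and validate a capture table
#'
#' Expects a delimited table with one row per fish handled at one occasion.
#' Rows for species outside `species_set` are dropped with a message.
#'
#' @param path CSV with columns `tag_id`, `species`, `occasion`, `section`,
#'   `total_length_mm`.
#' @param species_set character vector of target species.
#' @param n_occasions,n_sections optional bounds; out-of-range indices are a
#'   validation error naming the offending row.
#' @return validated capture data.frame (possibly zero rows).
#' @export
read_captures <- function(path, species_set, n_occasions = NULL,
                          n_sections = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "species", "occasion", "section", "total_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("capture table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  dropped <- sum(!(df$species %in% species_set))
  if (dropped > 0) {
    message("read_captures: dropped ", dropped, " row(s) of non-target species")
    df <- df[df$species %in% species_set, , drop = FALSE]
  }
  validate_captures(df, n_occasions = n_occasions, n_sections = n_sections)
}

#' @rdname read_captures
#' @param captures an in-memory capture data.frame to validate.
#' @export
validate_captures <- function(captures, n_occasions = NULL,
                              n_sections = NULL) {
  bad <- which(!is.finite(captures$total_length_mm) |
                 captures$total_length_mm <= 0)
  if (length(bad)) stop("non-positive total_length_mm at row ", bad[1])
  bad <- which(captures$occasion < 1 |
                 (if (is.null(n_occasions)) FALSE
                  else captures$occasion > n_occasions))
  if (length(bad)) stop("occasion out of range at row ", bad[1])
  bad <- which(captures$section < 1 |
                 (if (is.null(n_sections)) FALSE
                  else captures$section > n_sections))
  if (length(bad)) stop("section out of range at row ", bad[1])
  key <- paste(captures$tag_id, captures$occasion)
  if (anyDuplicated(key))
    stop("duplicate (tag_id, occasion): ", key[anyDuplicated(key)])
  rownames(captures) <- NULL
  captures
}

#' @rdname read_captures
#' @export
write_captures <- function(captures, path) {
  write.csv(captures, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-occasion habitat table
#'
#' Columns beyond those the model uses (e.g. width, depth, substrate) are
#' accepted and ignored.
#'
#' @param path CSV with columns `occasion`, `section`, `area_m2`, `hra_m2`,
#'   `velocity_ms`.
#' @return data.frame with the five model columns.
#' @export
read_habitat <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("occasion", "section", "area_m2", "hra_m2", "velocity_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("habitat table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$area_m2 <= 0)) stop("non-positive section area")
  if (any(df$hra_m2 < 0) || any(df$velocity_ms < 0))
    stop("negative habitat value")
  df[, need]
}

#' Movement replicates from capture histories
#'
#' The unit of the likelihood: one capture of a tagged individual at
#' occasion t paired with the next occasion. Under the default
#' `strict_consecutive` pairing every capture at t < T yields one replicate;
#' the recapture state Y is 1 (with observed end location) when the
#' individual was captured again at t + 1 and 0 (end location latent)
#' otherwise, and an individual reappearing after a skipped occasion seeds a
#' fresh replicate. The alternative `next_capture` pairing joins each
#' capture to the individual's next capture at any later occasion, with eta
#' the actually elapsed days.
#'
#' @param captures validated capture data.frame (see [read_captures()]).
#' @param occasions occasion table from [make_occasions()].
#' @param pairing `"strict_consecutive"` (default) or `"next_capture"`.
#' @param section_length section length in meters used for midpoints.
#' @return data.frame with columns `replicate_id`, `tag_id`, `species`,
#'   `occasion`, `section`, `x0`, `x1` (NA when Y = 0), `y`, `eta_days`,
#'   `total_length_mm`.
#' @export
build_replicates <- function(captures, occasions,
                             pairing = c("strict_consecutive", "next_capture"),
                             section_length = 10) {
  pairing <- match.arg(pairing)
  captures <- validate_captures(captures, n_occasions = nrow(occasions))
  n_occ <- nrow(occasions)
  ord <- order(captures$tag_id, captures$occasion)
  cap <- captures[ord, , drop = FALSE]
  reps <- vector("list", nrow(cap))
  for (i in seq_len(nrow(cap))) {
    t0 <- cap$occasion[i]
    if (t0 >= n_occ) next
    later <- which(cap$tag_id == cap$tag_id[i] & cap$occasion > t0)
    if (pairing == "strict_consecutive") {
      hit <- later[cap$occasion[later] == t0 + 1]
      eta <- occasions$interval_to_next[t0]
    } else {
      hit <- later[which.min(cap$occasion[later])]
      eta <- if (length(hit)) {
        sum(occasions$interval_to_next[t0:(cap$occasion[hit] - 1)])
      } else {
        occasions$interval_to_next[t0]
      }
    }
    y <- as.integer(length(hit) > 0)
    reps[[i]] <- data.frame(
      tag_id = cap$tag_id[i], species = cap$species[i],
      occasion = t0, section = cap$section[i],
      x0 = section_midpoint(cap$section[i], section_length),
      x1 = if (y == 1) section_midpoint(cap$section[hit[1]], section_length)
           else NA_real_,
      y = y, eta_days = eta,
      total_length_mm = cap$total_length_mm[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, reps)
  if (is.null(out)) {
    out <- data.frame(tag_id = character(), species = character(),
                      occasion = integer(), section = integer(),
                      x0 = numeric(), x1 = numeric(), y = integer(),
                      eta_days = numeric(), total_length_mm = numeric())
  }
  out <- out[order(out$species, out$tag_id, out$occasion), , drop = FALSE]
  out$replicate_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("replicate_id", "tag_id", "species", "occasion", "section",
          "x0", "x1", "y", "eta_days", "total_length_mm")]
}

#' Per-species capture and recapture tallies
#'
#' Reproduces the bookkeeping of a mark-recapture summary table: unique
#' individuals tagged, unique individuals recaptured in consecutive
#' surveys, replicate captures (individual-by-occasion events entering the
#' model), and replicate recaptures (Y = 1 events). Both the
#' distinct-individual and event-level recapture tallies are reported.
#'
#' @param replicates output of [build_replicates()] under
#'   `strict_consecutive` pairing.
#' @param captures the capture table the replicates were built from.
#' @return data.frame with one row per species.
#' @export
replicate_tallies <- function(replicates, captures) {
  species <- sort(unique(captures$species))
  out <- lapply(species, function(sp) {
    cap <- captures[captures$species == sp, , drop = FALSE]
    rep <- replicates[replicates$species == sp, , drop = FALSE]
    data.frame(
      species = sp,
      unique_tagged = length(unique(cap$tag_id)),
      unique_recaptured = length(unique(rep$tag_id[rep$y == 1])),
      replicate_captures = nrow(cap),
      replicate_recaptures = sum(rep$y == 1)
    )
  })
  do.call(rbind, out)
}
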