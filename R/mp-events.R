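#' Mass-photometry event sets
#'
#' An `mp_events` object holds the one-dimensional sample of single-particle
#' landing-event magnitudes produced by a mass photometer: either calibrated
#' masses in kDa (`kind = "mass"`) or raw ratiometric contrasts
#' (`kind = "contrast"`).  Values may be negative — unbinding events (a
#' particle leaving the coverslip) carry the opposite sign to landing
#' events.
#'
#' @param values numeric vector of event magnitudes; all finite.
#' @param kind `"mass"` (kDa) or `"contrast"` (dimensionless).
#' @param source provenance string (file path or `"synthetic"`).
#' @param meta named list of free-form acquisition metadata.
#'
#' @return An object of class `mp_events` with fields `values`, `kind`,
#'   `source` and `meta`.
#' @examples
#' ev <- mp_events(c(66, 146, 480), kind = "mass")
#' length(ev$values)
#' @export
mp_events <- function(values, kind = c("mass", "contrast"),
                      source = "unknown", meta = list()) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("event values must all be finite", call. = FALSE)
  structure(
    list(values = values, kind = kind, source = source, meta = meta),
    class = "mp_events"
  )
}

#' @export
print.mp_events <- function(x, ...) {
  cat(sprintf("Mass photometry events: n = %d (%s units), source: %s\n",
              length(x$values), x$kind, x$source))
  if (length(x$values)) {
    neg <- sum(x$values < 0)
    cat(sprintf("  binding %d | unbinding %d | range [%.4g, %.4g]\n",
                length(x$values) - neg, neg,
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Read mass-photometry events from an HDF5 or CSV export
#'
#' Loads the fitted-events table written by acquisition software (the
#' `eventsFitted` HDF5 layout, holding a one-dimensional dataset of masses
#' or contrasts) or a one-column CSV of event values.  When the HDF5 file
#' holds a mass dataset the result has `kind = "mass"`; when only a
#' `"contrasts"` dataset is present the raw contrasts are returned
#' (`kind = "contrast"`) for later conversion with [apply_calibration()].
#'
#' @param path path to a `.h5`/`.hdf5` file or a CSV/TSV file.
#' @param dataset_preference character vector of HDF5 dataset names to try,
#'   in order.  Names other than `"contrasts"` are treated as masses in kDa.
#' @return An [mp_events] object.  Values are preserved exactly as stored.
#' @seealso [gen_mp_events()] to create synthetic event sets,
#'   [write_mp_events()] for the inverse operation.
#' @export
read_mp_events <- function(path,
                           dataset_preference = c("masses_kDa", "masses",
                                                  "contrasts")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    read_mp_events_h5(path, dataset_preference)
  } else {
    read_mp_events_csv(path)
  }
}

read_mp_events_h5 <- function(path, dataset_preference) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 event files requires the 'rhdf5' package",
         call. = FALSE)
  contents <- rhdf5::h5ls(path)
  available <- contents$name[contents$otype == "H5I_DATASET"]
  hit <- dataset_preference[dataset_preference %in% available]
  if (!length(hit))
    stop(sprintf(
      "no recognized event dataset in '%s'; searched for: %s; file has: %s",
      path, paste(dataset_preference, collapse = ", "),
      paste(available, collapse = ", ")), call. = FALSE)
  name <- hit[[1L]]
  values <- as.numeric(rhdf5::h5read(path, name))
  kind <- if (identical(name, "contrasts")) "contrast" else "mass"
  mp_events(values, kind = kind, source = path,
            meta = list(dataset = name))
}

read_mp_events_csv <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]][1L])))
  tab <- utils::read.table(path, header = has_header, sep = sep)
  col <- tab[[1L]]
  if (!is.numeric(col))
    stop(sprintf("first column of '%s' is not numeric", path),
         call. = FALSE)
  kind <- "mass"
  if (has_header && grepl("contrast", names(tab)[1L], ignore.case = TRUE))
    kind <- "contrast"
  mp_events(as.numeric(col), kind = kind, source = path)
}

#' Write mass-photometry events to CSV or HDF5
#'
#' @param events an [mp_events] object.
#' @param path destination; `.h5`/`.hdf5` selects HDF5 (dataset named
#'   `masses_kDa` or `contrasts` by kind), anything else a one-column CSV.
#' @return `path`, invisibly.
#' @export
write_mp_events <- function(events, path) {
  stopifnot(inherits(events, "mp_events"))
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing HDF5 event files requires the 'rhdf5' package",
           call. = FALSE)
    name <- if (events$kind == "mass") "masses_kDa" else "contrasts"
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(events$values, path, name)
    rhdf5::h5closeAll()
  } else {
    header <- if (events$kind == "mass") "mass_kDa" else "contrast"
    utils::write.table(
      stats::setNames(data.frame(events$values), header),
      path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Event-count quality checks
#'
#' Flags acquisitions whose event count falls outside the usable regime and
#' reports the binding:unbinding ratio.  For the regular field of view the
#' recommended maximum is 3000 counts; crowded fields produce overlapping
#' landing events and unreliable masses, while very sparse acquisitions give
#' noisy histograms.
#'
#' @param events an [mp_events] object.
#' @param fov field-of-view setting, one of `"regular"`, `"medium"`,
#'   `"large"`.  The 3000-count ceiling applies to the regular FOV; wider
#'   fields scale it by area (factor 2 / 4 as shipped defaults).
#' @param min_count floor below which the acquisition is flagged sparse.
#' @return A list with `n`, `n_binding`, `n_unbinding`,
#'   `binding_unbinding_ratio` (`Inf` when no unbinding events), logical
#'   flags `too_many` / `too_few`, and `max_recommended`.
#' @examples
#' qc_event_count(mp_events(rep(100, 50)))$too_few
#' @export
qc_event_count <- function(events, fov = c("regular", "medium", "large"),
                           min_count = 100) {
  stopifnot(inherits(events, "mp_events"))
  fov <- match.arg(fov)
  max_rec <- c(regular = 3000, medium = 6000, large = 12000)[[fov]]
  v <- events$values
  n_bind <- sum(v > 0)
  n_unbind <- sum(v < 0)
  list(
    n = length(v),
    n_binding = n_bind,
    n_unbinding = n_unbind,
    binding_unbinding_ratio = if (n_unbind == 0) Inf else n_bind / n_unbind,
    too_many = length(v) > max_rec,
    too_few = length(v) < min_count,
    max_recommended = max_rec,
    fov = fov
  )
}
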