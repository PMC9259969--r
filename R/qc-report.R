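#' Decision thresholds for the quality-control report
#'
#' Numeric thresholds the decision tree applies to the per-technique
#' results.  All defaults are this package's own, overridable choices:
#' minimum acceptable melting temperature 45 °C, maximum polydispersity
#' index 0.3, at most 5% of scattered intensity above 100 nm, a 10%
#' relative tolerance when matching a mass-photometry component to the
#' expected mass, at least 50% of observable events in the target
#' species, and a usable event count between 100 and 3000.
#'
#' @param min_tm minimum dominant melting temperature, °C.
#' @param min_delta_tm minimum stabilization vs the reference condition,
#'   °C (0 disables the check).
#' @param max_pdi maximum cumulant polydispersity index.
#' @param max_aggregate_percent maximum intensity percent above the
#'   aggregate cutoff radius.
#' @param aggregate_cutoff_radius aggregate cutoff, nm.
#' @param mass_tolerance relative tolerance for matching a fitted mass
#'   component to the expected mass, in (0, 1).
#' @param min_target_species_fraction minimum fraction of observable
#'   events in the matching component, in (0, 1).
#' @param min_event_count,max_event_count usable acquisition size.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_tm = 45, min_delta_tm = 0, max_pdi = 0.3,
                          max_aggregate_percent = 5,
                          aggregate_cutoff_radius = 100,
                          mass_tolerance = 0.10,
                          min_target_species_fraction = 0.50,
                          min_event_count = 100,
                          max_event_count = 3000) {
  th <- list(min_tm = min_tm, min_delta_tm = min_delta_tm,
             max_pdi = max_pdi,
             max_aggregate_percent = max_aggregate_percent,
             aggregate_cutoff_radius = aggregate_cutoff_radius,
             mass_tolerance = mass_tolerance,
             min_target_species_fraction = min_target_species_fraction,
             min_event_count = min_event_count,
             max_event_count = max_event_count)
  if (!all(vapply(th, is.finite, logical(1))))
    stop("all thresholds must be finite", call. = FALSE)
  if (mass_tolerance <= 0 || mass_tolerance >= 1 ||
      min_target_species_fraction <= 0 || min_target_species_fraction >= 1)
    stop("tolerances must lie in (0, 1)", call. = FALSE)
  structure(th, class = "qc_thresholds")
}

#' Combine per-technique results into a go/no-go recommendation
#'
#' Walks the screening pipeline in its bench order — nanoDSF (stability),
#' DLS (dispersity/aggregation), mass photometry (mass distribution and
#' oligomeric state) — assigning each supplied technique a verdict of
#' `pass`, `warn` or `fail` with numeric evidence, then recommends a next
#' step.  Any failure stops the pipeline at that stage and recommends its
#' remedy: buffer/detergent optimization for an unstable protein,
#' re-purification or reconstitution for an aggregated or mass-deviant
#' sample.  A fitted mass component *above* the expected mass within no
#' tolerance is only a warning, not a failure: detergent-solubilized
#' membrane proteins routinely run heavy by a micelle's worth of mass.
#' Only an all-pass (or pass/warn) report yields a proceed recommendation
#' — negative staining first, or straight to cryo-EM grids when negative
#' staining has already been cleared.
#'
#' @param dsf optional `dsf_result` (see [analyze_dsf()]).
#' @param dls optional [size_distribution], or a list with elements
#'   `distribution` (a [size_distribution]) and optionally `pdi` (from
#'   [fit_cumulants()]).
#' @param mp optional `mp_mixture_fit` (see [fit_truncated_mixture()]).
#' @param expected_mass expected target mass in kDa (required with `mp`).
#' @param mp_qc optional [qc_event_count()] result for the acquisition.
#' @param thresholds a [qc_thresholds] object.
#' @param negative_stain_ok set `TRUE` once negative staining has shown
#'   well-dispersed particles; upgrades the proceed recommendation to
#'   cryo-EM grid preparation.
#' @return An object of class `qc_report`: `verdicts` (named list of
#'   `list(verdict, evidence)` in pipeline order), `recommendation`,
#'   `thresholds`, `provenance` (config hash and package version).
#' @export
evaluate_decision_tree <- function(dsf = NULL, dls = NULL, mp = NULL,
                                   expected_mass = NULL, mp_qc = NULL,
                                   thresholds = qc_thresholds(),
                                   negative_stain_ok = FALSE) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(dsf) && is.null(dls) && is.null(mp))
    stop("at least one technique result must be supplied", call. = FALSE)
  verdicts <- list()

  if (!is.null(dsf)) verdicts$dsf <- verdict_dsf(dsf, thresholds)
  if (!is.null(dls)) verdicts$dls <- verdict_dls(dls, thresholds)
  if (!is.null(mp))
    verdicts$mp <- verdict_mp(mp, expected_mass, mp_qc, thresholds)

  remedies <- c(dsf = "optimize-buffer/detergent",
                dls = "re-purify/reconstitute",
                mp = "re-purify/reconstitute")
  failing <- names(verdicts)[vapply(verdicts, function(v)
    v$verdict == "fail", logical(1))]
  recommendation <- if (length(failing)) {
    remedies[[failing[1L]]]
  } else if (negative_stain_ok) {
    "proceed-to-cryoEM-grids"
  } else {
    "proceed-to-negative-stain"
  }

  cfg <- jsonlite::toJSON(unclass(thresholds), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(as.character(cfg), tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)

  structure(
    list(verdicts = verdicts, recommendation = recommendation,
         thresholds = unclass(thresholds),
         provenance = list(
           config_hash = hash,
           package = "vitriqc",
           version = as.character(utils::packageVersion("vitriqc")))),
    class = "qc_report"
  )
}

verdict_dsf <- function(dsf, th) {
  stopifnot(inherits(dsf, "dsf_result"))
  evidence <- character(0)
  verdict <- "pass"
  if (is.na(dsf$tm)) {
    verdict <- "fail"
    evidence <- "no melting transition detected"
  } else {
    evidence <- sprintf("dominant Tm %.1f degC (threshold %.1f degC)",
                        dsf$tm, th$min_tm)
    if (dsf$tm < th$min_tm) verdict <- "fail"
  }
  if (!is.na(dsf$t_onset_agg)) {
    evidence <- c(evidence,
                  sprintf("aggregation onset %.1f degC", dsf$t_onset_agg))
    if (!is.na(dsf$tm) && dsf$t_onset_agg < th$min_tm) {
      evidence <- c(evidence, sprintf(
        "onset below the %.1f degC stability threshold", th$min_tm))
      if (verdict == "pass") verdict <- "warn"
    }
  }
  if (!isTRUE(dsf$initial_fluorescence_ok)) {
    evidence <- c(evidence, "initial fluorescence outside 2000-15000 counts")
    if (verdict == "pass") verdict <- "warn"
  }
  list(verdict = verdict, evidence = evidence)
}

verdict_dls <- function(dls, th) {
  dist <- if (inherits(dls, "size_distribution")) dls else dls$distribution
  pdi <- if (inherits(dls, "size_distribution")) NULL else dls$pdi
  stopifnot(inherits(dist, "size_distribution"))
  agg <- detect_aggregation(dist,
                            cutoff_radius = th$aggregate_cutoff_radius,
                            max_percent = th$max_aggregate_percent)
  peaks <- extract_peaks(dist, min_percent = 5)
  evidence <- agg$message
  verdict <- if (agg$flagged) "fail" else "pass"
  if (nrow(peaks) > 1L) {
    evidence <- c(evidence, sprintf(
      "%d resolved populations (largest at %.1f nm, %.0f%%)",
      nrow(peaks), peaks$rh_mean[which.max(peaks$percent)],
      max(peaks$percent)))
    if (verdict == "pass") verdict <- "warn"
  }
  if (!is.null(pdi) && is.finite(pdi)) {
    evidence <- c(evidence, sprintf("PDI %.3f (threshold %.2f)", pdi,
                                    th$max_pdi))
    if (pdi > th$max_pdi && verdict == "pass") verdict <- "warn"
  }
  list(verdict = verdict, evidence = evidence)
}

verdict_mp <- function(mp, expected_mass, mp_qc, th) {
  stopifnot(inherits(mp, "mp_mixture_fit"))
  if (is.null(expected_mass))
    stop("`expected_mass` is required to judge a mass-photometry fit",
         call. = FALSE)
  comp <- mp$components
  dev <- abs(comp$mu - expected_mass) / expected_mass
  evidence <- character(0)
  hit <- which(dev <= th$mass_tolerance)
  if (length(hit)) {
    hit <- hit[which.max(comp$fraction[hit])]
    evidence <- sprintf(
      "component at %.0f kDa matches expected %.0f kDa (%.1f%% deviation, %.0f%% of events)",
      comp$mu[hit], expected_mass, 100 * dev[hit],
      100 * comp$fraction[hit])
    verdict <- if (comp$fraction[hit] >= th$min_target_species_fraction)
      "pass" else "warn"
    if (verdict == "warn")
      evidence <- c(evidence, sprintf(
        "target species only %.0f%% of events (threshold %.0f%%)",
        100 * comp$fraction[hit], 100 * th$min_target_species_fraction))
  } else if (any(comp$mu > expected_mass)) {
    ## heavier than expected: plausibly a protein-micelle complex
    j <- which(comp$mu > expected_mass)
    j <- j[which.max(comp$fraction[j])]
    verdict <- "warn"
    evidence <- sprintf(
      paste0("component at %.0f kDa exceeds expected %.0f kDa by %.0f%% ",
             "(detergent-shifted mass; micelle contribution likely)"),
      comp$mu[j], expected_mass, 100 * dev[j])
  } else {
    verdict <- "fail"
    evidence <- sprintf(
      "no component within %.0f%% of expected %.0f kDa (closest %.0f kDa)",
      100 * th$mass_tolerance, expected_mass,
      comp$mu[which.min(dev)])
  }
  if (!is.null(mp_qc)) {
    if (isTRUE(mp_qc$too_many)) {
      evidence <- c(evidence, sprintf(
        "%d events exceed the recommended maximum %d", mp_qc$n,
        mp_qc$max_recommended))
      if (verdict == "pass") verdict <- "warn"
    }
    if (isTRUE(mp_qc$too_few)) {
      evidence <- c(evidence,
                    sprintf("only %d events acquired", mp_qc$n))
      if (verdict == "pass") verdict <- "warn"
    }
  }
  list(verdict = verdict, evidence = evidence)
}

#' Render a QC report as JSON or markdown
#'
#' Deterministic serialization of a [evaluate_decision_tree()] report.
#' The JSON form round-trips losslessly through [parse_qc_report()];
#' the markdown form lists the verdicts in pipeline order with their
#' evidence and the recommended next step.  Techniques that were not run
#' are omitted entirely.
#'
#' @param report a `qc_report`.
#' @param format `"json"` or `"markdown"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  stopifnot(inherits(report, "qc_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(unclass(report),
                                         auto_unbox = TRUE, pretty = TRUE,
                                         digits = NA)))
  }
  lines <- c("# Sample quality-control report", "")
  titles <- c(dsf = "nanoDSF (thermal stability)",
              dls = "DLS (dispersity)",
              mp = "Mass photometry (mass distribution)")
  for (tech in c("dsf", "dls", "mp")) {
    v <- report$verdicts[[tech]]
    if (is.null(v)) next
    lines <- c(lines, sprintf("## %s: %s", titles[[tech]],
                              toupper(v$verdict)),
               paste0("- ", v$evidence), "")
  }
  lines <- c(lines, sprintf("**Recommendation:** %s", report$recommendation),
             "", sprintf("_config %s, %s %s_",
                         report$provenance$config_hash,
                         report$provenance$package,
                         report$provenance$version))
  paste(lines, collapse = "\n")
}

#' @rdname render_report
#' @param json a JSON document produced by `render_report(..., "json")`.
#' @export
parse_qc_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  structure(x, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
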