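# DNA-content normalisation and rectangular phase gating.
#
# All gate intervals are half-open [low, high): a value exactly at a
# boundary belongs to the upper gate, and with ordered gate evaluation a
# cell is counted exactly once.

#' Estimate the G1 peak of a DNA-sum distribution
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of the integrated-DNA distribution; the G1 peak is the
#' lowest-intensity *major* mode, where major means density at least 25%
#' of the global maximum.  This returns the 1c mode even when the G2 peak
#' is taller.  In the standard workflow the peak is estimated from pooled
#' untreated control wells and applied plate-wide; pass a known value
#' straight to [normalise_dna()] to override.
#'
#' @param dna_sums Positive numeric vector of integrated DNA intensities.
#' @param min_events Warn if fewer events than this are supplied.
#' @param major_frac Fraction of the maximum density a mode must reach to
#'   count as major.
#' @return Scalar peak location (same units as `dna_sums`).
#' @export
estimate_g1_peak <- function(dna_sums, min_events = 500, major_frac = 0.25) {
  dna_sums <- dna_sums[is.finite(dna_sums)]
  if (!length(dna_sums)) stop("no DNA values supplied")
  if (any(dna_sums <= 0)) stop("DNA sums must be positive")
  if (length(dna_sums) < min_events)
    warning(sprintf("only %d events; G1 peak estimate may be unstable (< %d)",
                    length(dna_sums), min_events))
  if (diff(range(dna_sums)) == 0) return(dna_sums[1])
  d <- density(dna_sums, bw = bw.nrd0(dna_sums), n = 2048)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                       y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  major <- is_peak & y >= major_frac * max(y)
  if (!any(major)) major <- is_peak
  d$x[which(major)[1]]
}

#' Normalise DNA content to the G1 peak
#'
#' Adds `norm_dna = dna_sum / g1_peak`, so G1 cells centre at 1 and G2/M
#' at 2 (the flow-cytometry convention).
#'
#' @param records Tibble with a `dna_sum` column.
#' @param g1_peak Positive scalar, typically from [estimate_g1_peak()] on
#'   pooled control wells.
#' @return `records` with a `norm_dna` column.
#' @export
normalise_dna <- function(records, g1_peak) {
  if (!is.numeric(g1_peak) || length(g1_peak) != 1 || g1_peak <= 0)
    stop("g1_peak must be a positive scalar")
  if (!"dna_sum" %in% names(records)) stop("records lack a dna_sum column")
  dplyr::mutate(records, norm_dna = .data$dna_sum / g1_peak)
}

#' Log-transform EdU intensity
#'
#' Adds `log_edu = log10(edu_sum)`.  Non-positive values (possible after
#' background subtraction) are clamped to one tenth of the smallest
#' positive value and the number of clamped records is reported in a
#' warning and in the `n_clamped` attribute.
#'
#' @param records Tibble with an `edu_sum` column.
#' @return `records` with a `log_edu` column.
#' @export
log_edu <- function(records) {
  if (!"edu_sum" %in% names(records)) stop("records lack an edu_sum column")
  v <- records$edu_sum
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    floor_val <- min(v[!bad & !is.na(v)]) / 10
    if (!is.finite(floor_val) || floor_val <= 0) floor_val <- .Machine$double.eps
    v[bad] <- floor_val
    warning(sprintf("%d non-positive EdU value(s) clamped to %g", sum(bad),
                    floor_val))
  }
  out <- dplyr::mutate(records, log_edu = log10(v))
  attr(out, "n_clamped") <- sum(bad)
  out
}

#' Construct a gate specification
#'
#' A gate specification maps each phase to a set of half-open intervals
#' `[low, high)` over derived features (`norm_dna`, `log_edu`,
#' `phh3_mean`, `ki67_mean`, `marker_mean`); phases are evaluated in
#' priority order and the first gate containing a record wins.  Records
#' matching no gate are labelled `"unclassified"`.
#'
#' @param gates Named list: phase -> named list of feature -> `c(low, high)`
#'   (`-Inf`/`Inf` allowed).
#' @param priority Phase evaluation order; defaults to the order of
#'   `gates`.
#' @param mode Label describing the gating mode.
#' @return Object of class `gate_spec`.
#' @seealso [gates_dna_only()], [gates_multiparametric()], [gates_g0()]
#'   for the shipped templates.
#' @export
gate_spec <- function(gates, priority = names(gates), mode = "custom") {
  stopifnot(is.list(gates), length(gates) > 0, !is.null(names(gates)))
  if (!setequal(priority, names(gates)))
    stop("priority must be a permutation of the gate names")
  for (ph in names(gates)) {
    for (feat in names(gates[[ph]])) {
      iv <- gates[[ph]][[feat]]
      if (length(iv) != 2 || !(iv[1] < iv[2]))
        stop(sprintf("gate %s/%s: need low < high", ph, feat))
    }
  }
  structure(list(gates = gates, priority = priority, mode = mode),
            class = "gate_spec")
}

#' DNA-only cell-cycle gates
#'
#' The classic DNA-content classification on normalised DNA:
#' sub-G1 below `cuts[1]`, G1, S and G2/M between successive cuts, and
#' >G2/M at or above `cuts[4]`.  Default cuts 0.75 / 1.25 / 1.75 / 2.5.
#'
#' @param cuts Four increasing boundaries on normalised DNA.
#' @return A [gate_spec()].
#' @export
gates_dna_only <- function(cuts = c(0.75, 1.25, 1.75, 2.5)) {
  stopifnot(length(cuts) == 4, all(diff(cuts) > 0))
  gate_spec(list(
    subG1   = list(norm_dna = c(0, cuts[1])),
    G1      = list(norm_dna = c(cuts[1], cuts[2])),
    S       = list(norm_dna = c(cuts[2], cuts[3])),
    `G2/M`  = list(norm_dna = c(cuts[3], cuts[4])),
    `>G2/M` = list(norm_dna = c(cuts[4], Inf))
  ), mode = "dna_only")
}

#' Multiparametric (DNA + EdU + pHH3) cell-cycle gates
#'
#' Template gates for the three-channel analysis, shipped with the
#' HT29-style defaults: G1 = normalised DNA in `dna_g1` (0.7-1.4), log
#' EdU sum in `edu_neg` (3.2-4.3) and pHH3 mean below `phh3_bound`
#' (300); S = log EdU sum at or above `edu_pos_bound`; M = pHH3 mean at
#' or above `phh3_bound` with 2c DNA; G2 analogous to G1 at 2c.  All
#' bounds are staining- and cell-line-dependent configuration, not
#' universal constants.  Priority: M, then S, then the DNA-defined
#' classes.
#'
#' @param dna_g1,dna_g2,dna_m Normalised-DNA windows for G1, G2 and M.
#' @param edu_neg Log10 EdU-sum window of the EdU-negative population.
#' @param edu_pos_bound Log10 EdU sum at or above which a cell is
#'   EdU-positive (S).
#' @param phh3_bound pHH3 mean at or above which a cell is mitotic.
#' @param subg1_max Normalised DNA below which a cell is sub-G1.
#' @param over_g2m_min Normalised DNA at or above which a cell is >G2/M.
#' @return A [gate_spec()].
#' @export
gates_multiparametric <- function(dna_g1 = c(0.7, 1.4), dna_g2 = c(1.4, 2.5),
                                  dna_m = c(1.4, 2.5),
                                  edu_neg = c(3.2, 4.3), edu_pos_bound = 4.5,
                                  phh3_bound = 300, subg1_max = 0.7,
                                  over_g2m_min = 2.5) {
  gate_spec(list(
    M  = list(phh3_mean = c(phh3_bound, Inf), norm_dna = dna_m),
    S  = list(log_edu = c(edu_pos_bound, Inf)),
    G1 = list(norm_dna = dna_g1, log_edu = edu_neg,
              phh3_mean = c(-Inf, phh3_bound)),
    G2 = list(norm_dna = dna_g2, log_edu = edu_neg,
              phh3_mean = c(-Inf, phh3_bound)),
    subG1 = list(norm_dna = c(-Inf, subg1_max)),
    `>G2/M` = list(norm_dna = c(over_g2m_min, Inf))
  ), mode = "multiparametric")
}

#' Multiparametric gates with a Ki67-defined G0 population
#'
#' Extends [gates_multiparametric()] with a quiescent (G0) gate: the G1
#' gate conditions plus Ki67 mean below `ki67_bound` (default 200).  G0
#' takes priority over G1, so G1-gate cells at or above the Ki67 bound
#' remain G1.  Priority: M, G0, S, then the rest.
#'
#' @param ki67_bound Ki67 mean below which a 2n, EdU-negative,
#'   pHH3-negative cell is called G0.
#' @param ... Passed to [gates_multiparametric()].
#' @return A [gate_spec()].
#' @export
gates_g0 <- function(ki67_bound = 200, ...) {
  base <- gates_multiparametric(...)
  g0 <- c(base$gates$G1, list(ki67_mean = c(-Inf, ki67_bound)))
  gates <- append(base$gates, list(G0 = g0), after = 1)  # after M
  gate_spec(gates, priority = names(gates), mode = "multiparametric_g0")
}

#' Assign cell-cycle phases by rectangular gating
#'
#' Evaluates the gates of `spec` in priority order over the derived
#' feature columns; each record gets the first phase whose every interval
#' contains it (half-open: `low <= x < high`), or `"unclassified"`.
#'
#' @param records Tibble carrying the features the gates reference
#'   (e.g. `norm_dna`, `log_edu`, `phh3_mean`).
#' @param spec A [gate_spec()].
#' @return `records` with a `phase` factor column (levels = priority
#'   order plus `"unclassified"`).
#' @export
assign_phase <- function(records, spec) {
  stopifnot(inherits(spec, "gate_spec"))
  feats <- unique(unlist(lapply(spec$gates, names)))
  missing <- setdiff(feats, names(records))
  if (length(missing))
    stop("gates reference missing feature(s): ", paste(missing, collapse = ", "))
  n <- nrow(records)
  phase <- rep(NA_character_, n)
  for (ph in spec$priority) {
    g <- spec$gates[[ph]]
    ok <- rep(TRUE, n)
    for (feat in names(g)) {
      x <- records[[feat]]
      ok <- ok & !is.na(x) & x >= g[[feat]][1] & x < g[[feat]][2]
    }
    phase[is.na(phase) & ok] <- ph
  }
  phase[is.na(phase)] <- "unclassified"
  records$phase <- factor(phase, levels = c(spec$priority, "unclassified"))
  records
}

#' @rdname assign_phase
#' @details `assign_g0()` is [assign_phase()] with a G0-containing
#'   template ([gates_g0()]) as the default spec; it requires a
#'   `ki67_mean` column.
#' @export
assign_g0 <- function(records, spec = gates_g0()) {
  if (!"ki67_mean" %in% names(records)) stop("records lack a ki67_mean column")
  assign_phase(records, spec)
}

#' Phase distribution of gated records
#'
#' Counts and fractions per phase (unclassified included as its own
#' bucket, so fractions sum to 1), optionally per group.
#'
#' @param records Tibble with a `phase` column from [assign_phase()].
#' @param by Optional character vector of grouping columns (e.g.
#'   `"well"`).
#' @return Tibble with `phase`, `count`, `fraction` (and grouping
#'   columns).
#' @export
phase_distribution <- function(records, by = NULL) {
  stopifnot("phase" %in% names(records))
  out <- records |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "phase"))),
                 name = "count", .drop = FALSE) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  if (!is.null(by)) out <- dplyr::arrange(out,
                                          dplyr::across(dplyr::all_of(by)))
  out
}

#' Aggregate per-well phase distributions across replicates
#'
#' Mean and SD of the per-well phase fractions within each condition —
#' the "average of N technical replicates +/- SD" summary.
#'
#' @param records Gated per-cell tibble with `phase`, `well` and a
#'   condition column.
#' @param condition Name of the condition column.
#' @param well Name of the well column.
#' @return Tibble with condition, `phase`, `mean_fraction`,
#'   `sd_fraction`, `n_wells`.
#' @export
aggregate_phase_distribution <- function(records, condition = "condition",
                                         well = "well") {
  per_well <- phase_distribution(records, by = c(condition, well))
  per_well |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(condition, "phase")))) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction),
                     sd_fraction = sd(.data$fraction),
                     n_wells = dplyr::n(), .groups = "drop")
}

#' Phase distribution of a marker-positive subpopulation
#'
#' Filters records whose marker mean is at or above `bound` (e.g.
#' gammaH2AX-positive nuclei), gates the subset, and reports its phase
#' distribution together with the overall positive fraction.
#'
#' @param records Tibble with derived gating features.
#' @param marker Name of the marker-mean column (default `marker_mean`).
#' @param bound Positivity threshold (`-Inf` reproduces the full
#'   population).
#' @param spec Gate specification for the subset.
#' @return List: `distribution` (phase tibble), `fraction_positive`,
#'   `n_positive`, `n_total`.
#' @export
subpopulation_distribution <- function(records, marker = "marker_mean",
                                       bound, spec = gates_multiparametric()) {
  if (!marker %in% names(records)) stop("records lack column ", marker)
  pos <- records[[marker]] >= bound
  sub <- records[pos, , drop = FALSE]
  dist <- if (nrow(sub)) {
    phase_distribution(assign_phase(sub, spec))
  } else {
    d <- phase_distribution(assign_phase(records[0, , drop = FALSE], spec))
    d$fraction <- 0
    d
  }
  list(distribution = dist,
       fraction_positive = mean(pos),
       n_positive = sum(pos), n_total = length(pos))
}

#' Proliferation index from EdU positivity
#'
#' Ratio of the EdU-positive fraction in a treated population to that in
#' its control, plus the singlet counts (the per-well "cell number").
#'
#' @param treated,control Gated record tibbles with a `log_edu` column.
#' @param edu_pos_bound Log10 EdU sum at or above which a cell is
#'   EdU-positive.
#' @return One-row tibble: `proliferation_index`, per-arm EdU-positive
#'   fractions and cell counts.
#' @export
proliferation_index <- function(treated, control, edu_pos_bound = 4.5) {
  if (!nrow(treated) || !nrow(control)) stop("both populations must be non-empty")
  ft <- mean(treated$log_edu >= edu_pos_bound)
  fc <- mean(control$log_edu >= edu_pos_bound)
  if (fc == 0) stop("control population has no EdU-positive cells")
  tibble(proliferation_index = ft / fc,
         frac_edu_pos_treated = ft, frac_edu_pos_control = fc,
         n_treated = nrow(treated), n_control = nrow(control))
}

#' DNA-content histogram
#'
#' Bins normalised DNA into `bins` equal-width bins over `[0, max_dna)` —
#' the 300-bin flow-style histogram.
#'
#' @param records Tibble with `norm_dna`.
#' @param bins Number of bins.
#' @param max_dna Upper edge of the histogram range.
#' @return Tibble with `bin`, `mid`, `count`; counts sum to the number of
#'   in-range records.
#' @export
dna_histogram <- function(records, bins = 300, max_dna = 4) {
  stopifnot("norm_dna" %in% names(records), bins >= 1, max_dna > 0)
  x <- records$norm_dna
  x <- x[!is.na(x) & x >= 0 & x < max_dna]
  idx <- pmin(floor(x / max_dna * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  width <- max_dna / bins
  tibble(bin = seq_len(bins), mid = (seq_len(bins) - 0.5) * width,
         count = counts)
}
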