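# Plate-level orchestration: segment -> border filter -> features ->
# classify -> normalise (pooled controls) -> gate -> aggregate.

#' Define a plate layout
#'
#' @param wells Character vector of 96-well ids (`A1`-`H12`).
#' @param condition Condition label per well (recycled if length 1).
#' @param control Logical per well: is it an untreated control used for
#'   G1-peak normalisation? (recycled if length 1).
#' @param fields_per_well Fields imaged per well.
#' @param plate_id Optional plate identifier.
#' @return Tibble of class `plate_layout`.
#' @export
plate_layout <- function(wells, condition = "control", control = TRUE,
                         fields_per_well = 5L, plate_id = "plate1") {
  if (!all(grepl("^[A-H](1[0-2]|[1-9])$", wells)))
    stop("well ids must match the 96-well grid A1-H12")
  if (anyDuplicated(wells)) stop("duplicate well ids")
  out <- tibble(well = wells,
                condition = rep_len(condition, length(wells)),
                control = rep_len(control, length(wells)))
  structure(out, fields_per_well = as.integer(fields_per_well),
            plate_id = plate_id, class = c("plate_layout", class(out)))
}

#' Simulate a whole plate of fields
#'
#' One [simulate_field()] per well and field, with a deterministic
#' per-field seed offset so the plate is reproducible from a single seed
#' yet no two fields are identical.
#'
#' @param layout A [plate_layout()].
#' @param config A [simulation_config()]; `config$seed` seeds the plate.
#' @return Nested list `fields[[well]][[field]]`, each element as
#'   returned by [render_field()].
#' @export
simulate_plate <- function(layout, config) {
  stopifnot(inherits(layout, "plate_layout"), inherits(config, "simulation_config"))
  nf <- attr(layout, "fields_per_well")
  out <- lapply(seq_len(nrow(layout)), function(wi) {
    lapply(seq_len(nf), function(fi) {
      simulate_field(config, field_seed_offset = 101L * (wi - 1L) + fi)
    })
  })
  names(out) <- layout$well
  out
}

#' Run the full analysis pipeline on a plate
#'
#' For every field: optional flat-field correction, nuclear segmentation
#' ([find_nuclei()]), border-object removal, feature extraction
#' ([nucleus_features()]).  Pooled per plate: singlet classification,
#' G1-peak estimation from the singlets of control wells (applied
#' plate-wide), DNA normalisation, log-EdU, phase gating, and per-well /
#' per-condition aggregation.
#'
#' @param plate Nested field list from [simulate_plate()] or
#'   [read_plate()].
#' @param layout A [plate_layout()].
#' @param classifier A trained [train_singlet_classifier()] model.
#' @param gates A [gate_spec()].
#' @param method Segmentation preset, `"B"` or `"M"`.
#' @param flat_field Apply [flat_field_correct()] (estimated reference)
#'   to every channel before segmentation and measurement?
#' @param g1_peak Optional manual override of the G1 peak (skips
#'   estimation).
#' @param ... Further arguments to [find_nuclei()].
#' @return List of class `cyclegate_run`: `cells` (per-cell tibble with
#'   features, singlet flag, derived gating values and phase), `wells`
#'   (per-well phase distribution), `conditions` (mean +/- SD across
#'   replicate wells), `g1_peak`, and a run `manifest`.
#' @export
run_pipeline <- function(plate, layout, classifier, gates, method = "B",
                         flat_field = FALSE, g1_peak = NULL, ...) {
  stopifnot(inherits(layout, "plate_layout"), inherits(gates, "gate_spec"))
  if (!all(layout$well %in% names(plate)))
    stop("plate is missing wells: ",
         paste(setdiff(layout$well, names(plate)), collapse = ", "))
  needed <- gate_channels(gates)
  first <- plate[[layout$well[1]]][[1]]
  missing_ch <- setdiff(needed, names(first$channels))
  if (length(missing_ch))
    stop("gating mode needs channel(s) not present in the images: ",
         paste(missing_ch, collapse = ", "))

  cells <- purrr::map_dfr(layout$well, function(w) {
    purrr::map_dfr(seq_along(plate[[w]]), function(fi) {
      fld <- plate[[w]][[fi]]
      chans <- fld$channels
      if (flat_field) chans <- lapply(chans, flat_field_correct)
      lbl <- find_nuclei(chans$dna, method = method, ...)
      lbl <- remove_border_objects(lbl)
      nucleus_features(chans, lbl, well = w, field = fi)
    })
  })
  cells <- dplyr::left_join(cells, as_tibble(layout)[c("well", "condition")],
                            by = "well")
  cells <- classify_singlets(cells, classifier)
  singlets <- dplyr::filter(cells, .data$singlet)

  if (is.null(g1_peak)) {
    ctrl <- layout$well[layout$control]
    if (!length(ctrl))
      stop("per-plate normalisation needs at least one control well")
    ctrl_dna <- singlets$dna_sum[singlets$well %in% ctrl]
    g1_peak <- estimate_g1_peak(ctrl_dna)
  }
  singlets <- normalise_dna(singlets, g1_peak)
  if ("edu_sum" %in% names(singlets)) singlets <- log_edu(singlets)
  singlets <- assign_phase(singlets, gates)

  wells <- phase_distribution(singlets, by = c("condition", "well"))
  conditions <- aggregate_phase_distribution(singlets)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclegate")),
    g1_peak = g1_peak, gating_mode = gates$mode, method = method,
    n_fields = sum(lengths(plate[layout$well])),
    n_objects = nrow(cells), n_singlets = nrow(singlets),
    layout_hash = rlang::hash(as.data.frame(layout)),
    gates_hash = rlang::hash(gates)
  )
  structure(list(cells = cells, singlets = singlets, wells = wells,
                 conditions = conditions, g1_peak = g1_peak,
                 manifest = manifest),
            class = "cyclegate_run")
}

# channels a gate spec needs, from its feature names
gate_channels <- function(gates) {
  feats <- unique(unlist(lapply(gates$gates, names)))
  map <- c(norm_dna = "dna", log_edu = "edu", phh3_mean = "phh3",
           ki67_mean = "ki67", marker_mean = "marker")
  unname(map[intersect(names(map), feats)])
}

#' @export
print.cyclegate_run <- function(x, ...) {
  cat("cyclegate pipeline run\n")
  cat(sprintf("  %d objects, %d singlets; G1 peak %.1f AU; mode %s\n",
              x$manifest$n_objects, x$manifest$n_singlets, x$g1_peak,
              x$manifest$gating_mode))
  print(x$conditions)
  invisible(x)
}

#' @describeIn run_pipeline One-row summary of a pipeline run
#'   (broom-style).
#' @param x A `cyclegate_run`.
#' @export
glance.cyclegate_run <- function(x, ...) {
  tibble(n_objects = x$manifest$n_objects,
         n_singlets = x$manifest$n_singlets,
         g1_peak = x$g1_peak, gating_mode = x$manifest$gating_mode,
         method = x$manifest$method)
}

#' @describeIn run_pipeline Per-condition phase fractions in tidy form.
#' @export
tidy.cyclegate_run <- function(x, ...) x$conditions
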