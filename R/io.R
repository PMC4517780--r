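# File I/O: 16-bit TIFF fields, ground-truth CSV, YAML configs.
#
# Default file naming: <well>_f<field>_<channel>.tiff (the export naming
# of HCS instruments is site-configured; override with `pattern`).

TIFF_MAX <- 65535

field_file <- function(dir, well, field, what,
                       pattern = "%s_f%d_%s.tiff") {
  file.path(dir, sprintf(pattern, well, field, what))
}

#' Write a simulated or measured field to disk
#'
#' One 16-bit grayscale TIFF per channel, the ground-truth label map as a
#' 16-bit TIFF, and the ground-truth table as CSV.
#'
#' @param fld Field list (`channels`, optionally `labels` and `truth`).
#' @param dir Output directory (created if needed).
#' @param well,field Identifiers used in the file names.
#' @param pattern `sprintf` pattern for file names
#'   (well, field, channel).
#' @return Invisibly, the paths written.
#' @export
write_field <- function(fld, dir, well, field, pattern = "%s_f%d_%s.tiff") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(fld$channels)) {
    p <- field_file(dir, well, field, ch, pattern)
    x <- pmin(pmax(fld$channels[[ch]], 0), TIFF_MAX) / TIFF_MAX
    tiff::writeTIFF(x, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  if (!is.null(fld$labels)) {
    p <- field_file(dir, well, field, "labels", pattern)
    tiff::writeTIFF(fld$labels / TIFF_MAX, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  if (!is.null(fld$truth)) {
    p <- file.path(dir, sprintf("%s_f%d_truth.csv", well, field))
    utils::write.csv(fld$truth, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a field's channel TIFFs from disk
#'
#' @param dir Directory holding the TIFFs.
#' @param well,field Identifiers in the file names.
#' @param channels Channel names to read.
#' @param pattern `sprintf` pattern for file names.
#' @return Field list with `channels` (matrices in AU, i.e. the 16-bit
#'   values).
#' @export
read_field <- function(dir, well, field, channels = c("dna", "edu", "phh3"),
                       pattern = "%s_f%d_%s.tiff") {
  chans <- lapply(channels, function(ch) {
    p <- field_file(dir, well, field, ch, pattern)
    if (!file.exists(p)) stop("missing image: ", p)
    tiff::readTIFF(p) * TIFF_MAX
  })
  names(chans) <- channels
  list(channels = chans)
}

#' Write / read a whole simulated plate
#'
#' @param plate Nested field list from [simulate_plate()].
#' @param layout A [plate_layout()].
#' @param dir Directory.
#' @param channels Channels to read back.
#' @return `write_plate` returns `dir` invisibly; `read_plate` returns a
#'   nested field list suitable for [run_pipeline()].
#' @export
write_plate <- function(plate, layout, dir) {
  for (w in names(plate))
    for (fi in seq_along(plate[[w]]))
      write_field(plate[[w]][[fi]], dir, w, fi)
  invisible(dir)
}

#' @rdname write_plate
#' @export
read_plate <- function(dir, layout, channels = c("dna", "edu", "phh3")) {
  nf <- attr(layout, "fields_per_well")
  out <- lapply(layout$well, function(w)
    lapply(seq_len(nf), function(fi) read_field(dir, w, fi, channels)))
  names(out) <- layout$well
  out
}

#' Serialise / restore gate specifications as YAML
#'
#' @param spec A [gate_spec()].
#' @param path File path.
#' @return `gates_to_yaml` returns `path` invisibly; `gates_from_yaml`
#'   returns a [gate_spec()].
#' @export
gates_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "gate_spec"))
  obj <- list(mode = spec$mode, priority = as.list(spec$priority),
              gates = lapply(spec$gates, function(g)
                lapply(g, function(iv) list(low = iv[1], high = iv[2]))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname gates_to_yaml
#' @export
gates_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  gates <- lapply(obj$gates, function(g)
    lapply(g, function(iv) c(yaml_num(iv$low), yaml_num(iv$high))))
  gate_spec(gates, priority = unlist(obj$priority), mode = obj$mode)
}

# YAML has no native +/-Inf in all emitters; accept ".inf" strings
yaml_num <- function(x) {
  if (is.character(x)) {
    if (grepl("^-", x)) return(-Inf)
    return(Inf)
  }
  as.numeric(x)
}

#' Serialise / restore a simulation configuration as YAML
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `simulation_config_to_yaml` returns `path` invisibly;
#'   `simulation_config_from_yaml` returns a [simulation_config()].
#' @export
simulation_config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  obj <- unclass(config)
  obj$fractions <- as.list(unclass(obj$fractions))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname simulation_config_to_yaml
#' @export
simulation_config_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$fractions <- do.call(phase_fractions, obj$fractions)
  obj$clump_size_probs <- setNames(as.numeric(unlist(obj$clump_size_probs)),
                                   c("2", "3", "4"))
  obj$channels <- unlist(obj$channels)
  obj$marker_positive_phases <- as.character(unlist(obj$marker_positive_phases))
  obj$intensity_model <- lapply(obj$intensity_model, function(ch) lapply(ch, unlist))
  do.call(simulation_config, obj)
}
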