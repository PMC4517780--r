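# Per-nucleus morphology and intensity features.
#
# Definitions fixed for reproducibility within this package:
#  * perimeter: exposed 4-neighbour pixel-edge count scaled by pi/4
#    (Crofton-style diagonal correction; exact in expectation for smooth
#    convex shapes, so a disc has roundness -> 1)
#  * axial lengths: 4 * sqrt(eigenvalues) of the pixel-coordinate
#    covariance (+ 1/12 per-pixel variance), i.e. ellipse-equivalent
#    full axis lengths
#  * symmetry: fraction of mask pixels whose 180-degree rotation about
#    the centroid (rounded to the grid) is also in the mask
#  * threshold compactness: fraction of region pixels at or above 50% of
#    the region's robust (99th percentile) DNA intensity — a
#    bright-single-core detector

region_pixel_lists <- function(labels) {
  pos <- which(labels > 0L)
  if (!length(pos)) return(list())
  ids <- labels[pos]
  nr <- nrow(labels)
  rows <- ((pos - 1L) %% nr) + 1L
  cols <- ((pos - 1L) %/% nr) + 1L
  split(data.frame(row = rows, col = cols, pos = pos), ids)
}

region_morphology <- function(px, labels, dna) {
  n <- nrow(px)
  cr <- mean(px$row); cc <- mean(px$col)
  dr <- px$row - cr; dc <- px$col - cc
  # population covariance with per-pixel (unit square) variance 1/12
  cov <- matrix(c(mean(dr * dr) + 1 / 12, mean(dr * dc),
                  mean(dr * dc), mean(dc * dc) + 1 / 12), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])

  # perimeter: outer-boundary chain code with Kulpa's diagonal correction
  # (axial + sqrt(2)*diagonal steps, scaled by pi*(1+sqrt(2))/8), which is
  # asymptotically exact for smooth convex shapes
  r1 <- min(px$row); c1 <- min(px$col)
  mh <- max(px$row) - r1 + 3L; mw <- max(px$col) - c1 + 3L
  mask <- matrix(FALSE, mh, mw)
  mask[cbind(px$row - r1 + 2L, px$col - c1 + 2L)] <- TRUE
  oc <- EBImage::ocontour(matrix(as.integer(mask), mh, mw))[[1]]
  if (nrow(oc) >= 3) {
    st <- abs(diff(rbind(oc, oc[1, , drop = FALSE])))
    diag_step <- st[, 1] & st[, 2]
    perimeter <- (pi * (1 + sqrt(2)) / 8) *
      (sum(!diag_step) + sqrt(2) * sum(diag_step))
  } else {
    perimeter <- 2 * sqrt(pi * n)  # degenerate: treat as a tiny disc
  }
  roundness <- min(1, 4 * pi * n / perimeter^2)

  rr <- round(2 * cr - px$row) - r1 + 2L
  rc <- round(2 * cc - px$col) - c1 + 2L
  inside <- rr >= 1L & rr <= mh & rc >= 1L & rc <= mw
  symmetry <- sum(inside & mask[cbind(pmin(pmax(rr, 1L), mh),
                                      pmin(pmax(rc, 1L), mw))]) / n

  vals <- dna[px$pos]
  thr <- 0.5 * quantile(vals, 0.99, names = FALSE)
  compactness <- mean(vals >= thr)

  c(row = cr, col = cc, area = n, perimeter = perimeter,
    roundness = roundness, axial_major = major, axial_small = minor,
    axial_ratio = if (major > 0) minor / major else 1,
    symmetry = symmetry, compactness = compactness)
}

#' Morphology features per nucleus
#'
#' Computes, for every label in the map: centroid, area, perimeter,
#' roundness (4*pi*area / perimeter^2), ellipse-equivalent axial major
#' and small (minor) lengths and their ratio, 180-degree rotational
#' symmetry, and threshold compactness (see the feature definitions in
#' the package vignette).  The DNA image is only used for threshold
#' compactness.
#'
#' @param labels Integer label matrix.
#' @param dna DNA-channel intensity matrix, same shape.
#' @return Tibble, one row per label, ordered by `nucleus_id`.
#' @export
morphology_features <- function(labels, dna) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(dna)))
  regions <- region_pixel_lists(labels)
  if (!length(regions)) {
    return(tibble(nucleus_id = integer(), row = numeric(), col = numeric(),
                  area = numeric(), perimeter = numeric(), roundness = numeric(),
                  axial_major = numeric(), axial_small = numeric(),
                  axial_ratio = numeric(), symmetry = numeric(),
                  compactness = numeric()))
  }
  feats <- t(vapply(regions, region_morphology, numeric(10),
                    labels = labels, dna = dna))
  out <- as_tibble(feats)
  out$nucleus_id <- as.integer(names(regions))
  dplyr::relocate(out, "nucleus_id")
}

#' Per-nucleus intensity statistics for one channel
#'
#' @param labels Integer label matrix.
#' @param image Intensity matrix, same shape.
#' @param statistic `"sum"`, `"mean"`, or both.
#' @return Tibble with `nucleus_id` and the requested statistic columns.
#' @export
intensity_features <- function(labels, image, statistic = c("sum", "mean")) {
  stopifnot(is.matrix(labels), all(dim(labels) == dim(image)))
  statistic <- match.arg(statistic, several.ok = TRUE)
  pos <- labels > 0L
  ids <- labels[pos]
  if (!length(ids)) {
    out <- tibble(nucleus_id = integer())
    for (s in statistic) out[[s]] <- numeric()
    return(out)
  }
  sums <- rowsum(image[pos], ids)
  ns <- rowsum(rep(1, length(ids)), ids)
  out <- tibble(nucleus_id = as.integer(rownames(sums)))
  if ("sum" %in% statistic) out$sum <- as.numeric(sums)
  if ("mean" %in% statistic) out$mean <- as.numeric(sums / ns)
  out
}

#' Full per-nucleus feature table for a field
#'
#' Combines [morphology_features()] on the DNA channel with
#' [intensity_features()] (sum and mean) for every channel, producing the
#' per-cell record table consumed by the classifier and gating stages.
#' Channel columns are named `<channel>_sum` and `<channel>_mean`
#' (`mean = sum / area` exactly).
#'
#' @param channels Named list of channel matrices (must include `dna`).
#' @param labels Integer label matrix.
#' @param well,field Identifiers stamped onto every row.
#' @return Tibble, one row per nucleus.
#' @export
nucleus_features <- function(channels, labels, well = NA_character_,
                             field = NA_integer_) {
  if (!"dna" %in% names(channels)) stop("channels must include 'dna'")
  out <- morphology_features(labels, channels$dna)
  for (ch in names(channels)) {
    fx <- intensity_features(labels, channels[[ch]])
    names(fx)[-1] <- paste0(ch, c("_sum", "_mean"))
    out <- dplyr::left_join(out, fx, by = "nucleus_id")
  }
  dplyr::mutate(out, well = well, field = as.integer(field),
                .before = "nucleus_id")
}
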