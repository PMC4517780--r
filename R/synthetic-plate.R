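# Synthetic plate simulator: populations of elliptical nuclei with
# phase-dependent channel intensities, rendered into multichannel fields
# with a matching ground-truth label map.

#' Cell-cycle phase fractions
#'
#' Validated named vector of phase fractions for the population simulator.
#' Fractions must be non-negative and sum to 1 (within 1e-9).
#'
#' @param subG1,G1,S,G2,M,G0 Fraction of cells in each phase.
#' @return Named numeric vector of class `phase_fractions`.
#' @examples
#' phase_fractions(G1 = 0.5, S = 0.3, G2 = 0.15, M = 0.05)
#' @export
phase_fractions <- function(subG1 = 0, G1 = 0, S = 0, G2 = 0, M = 0, G0 = 0) {
  f <- c(subG1 = subG1, G1 = G1, S = S, G2 = G2, M = M, G0 = G0)
  if (any(f < 0)) stop("phase fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("phase fractions must sum to 1")
  structure(f, class = "phase_fractions")
}

default_intensity_model <- function() {
  # log10-normal (location, scale) per channel; "positive" and "negative"
  # populations separated by >= 10x in median, mirroring the bimodal
  # EdU / pHH3 scatter seen in asynchronous populations.
  list(
    dna  = list(g1_sum = 5000, cv = 0.04),
    edu  = list(neg = c(3.75, 0.12), pos = c(5.00, 0.12)),   # integrated sum
    phh3 = list(neg = c(1.70, 0.15), pos = c(3.30, 0.15)),   # per-pixel mean
    ki67 = list(neg = c(1.60, 0.15), pos = c(3.00, 0.15)),   # per-pixel mean
    marker = list(neg = c(1.70, 0.15), pos = c(3.00, 0.15))  # per-pixel mean
  )
}

#' Simulation configuration
#'
#' Parameters controlling one simulated field: geometry, population
#' structure, per-channel intensity models, noise and illumination.
#' Defaults emulate an asynchronous adherent cancer-cell line imaged at
#' low magnification: mean nucleus equivalent radius 8 px in a 512x512
#' field, integrated G1 DNA intensity 5000 AU with ~4% CV, EdU-positive
#' and pHH3-positive populations ~18x above their negative counterparts.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param n_cells Nuclei per field (before border clipping).
#' @param fractions A [phase_fractions()] vector.
#' @param channels Channels to render; subset of
#'   `c("dna", "edu", "phh3", "ki67", "marker")` (dna always included).
#' @param clump_fraction Fraction of nuclei placed in touching clumps.
#' @param clump_size_probs Probabilities of clump sizes 2, 3 and 4.
#' @param mean_radius Mean G1 nucleus equivalent radius, pixels.
#' @param axial_ratio_range Range of semi-axis ratio b/a drawn per nucleus.
#' @param overlap_factor Centre distance between clumped neighbours as a
#'   multiple of the sum of their minor semi-axes (< 1 forces mask overlap).
#' @param marker_positive_phases Phases whose cells draw the marker channel
#'   from the positive distribution (default none).
#' @param intensity_model Per-channel intensity parameters; see
#'   `cyclegate:::default_intensity_model()` for the structure.
#' @param background Additive background level, AU per pixel.
#' @param poisson_noise Apply Poisson (shot) noise to the signal?
#' @param read_noise_sd SD of additive Gaussian read noise, AU.
#' @param blur_sigma Gaussian PSF sigma, pixels.
#' @param illumination_falloff Amplitude in `[0, 1)` of a radial
#'   (parabolic) illumination falloff; 0 disables it.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(shape = c(512L, 512L),
                              n_cells = 100L,
                              fractions = phase_fractions(G1 = 0.5, S = 0.3,
                                                          G2 = 0.15, M = 0.05),
                              channels = c("dna", "edu", "phh3"),
                              clump_fraction = 0.1,
                              clump_size_probs = c(`2` = 0.7, `3` = 0.2, `4` = 0.1),
                              mean_radius = 8,
                              axial_ratio_range = c(0.7, 1.0),
                              overlap_factor = 0.85,
                              marker_positive_phases = character(),
                              intensity_model = default_intensity_model(),
                              background = 5,
                              poisson_noise = TRUE,
                              read_noise_sd = 2,
                              blur_sigma = 0.6,
                              illumination_falloff = 0,
                              seed = 1L) {
  if (n_cells <= 0) stop("n_cells must be positive")
  if (!inherits(fractions, "phase_fractions")) fractions <- do.call(phase_fractions, as.list(fractions))
  if (clump_fraction < 0 || clump_fraction > 1) stop("clump_fraction must be in [0, 1]")
  if (illumination_falloff < 0 || illumination_falloff >= 1)
    stop("illumination_falloff must be in [0, 1)")
  if (mean_radius <= 0 || blur_sigma < 0 || background < 0 || read_noise_sd < 0)
    stop("scales must be non-negative and mean_radius positive")
  channels <- union("dna", match.arg(channels, c("dna", "edu", "phh3", "ki67", "marker"),
                                     several.ok = TRUE))
  structure(list(
    shape = as.integer(shape), n_cells = as.integer(n_cells),
    fractions = fractions, channels = channels,
    clump_fraction = clump_fraction, clump_size_probs = clump_size_probs,
    mean_radius = mean_radius, axial_ratio_range = axial_ratio_range,
    overlap_factor = overlap_factor,
    marker_positive_phases = marker_positive_phases,
    intensity_model = intensity_model,
    background = background, poisson_noise = poisson_noise,
    read_noise_sd = read_noise_sd, blur_sigma = blur_sigma,
    illumination_falloff = illumination_falloff, seed = as.integer(seed)
  ), class = "simulation_config")
}

rlnorm10 <- function(n, par) 10^rnorm(n, par[1], par[2])

draw_dna_content <- function(phase, im) {
  n <- length(phase)
  content <- numeric(n)
  cv <- im$dna$cv
  g1_like <- phase %in% c("G1", "G0")
  g2_like <- phase %in% c("G2", "M")
  content[g1_like] <- rlnorm(sum(g1_like), meanlog = log(1), sdlog = cv)
  content[g2_like] <- rlnorm(sum(g2_like), meanlog = log(2), sdlog = cv)
  content[phase == "S"] <- runif(sum(phase == "S"), 1, 2)
  content[phase == "subG1"] <- runif(sum(phase == "subG1"), 0.3, 0.7)
  content
}

#' Sample a simulated nucleus population
#'
#' Draws phases from a multinomial over the configured fractions and, for
#' each nucleus, its geometry (elliptical, mild eccentricity), true DNA
#' content (G1 = 1x, S uniform in (1, 2), G2/M = 2x), per-channel true
#' integrated intensities, and placement.  A configurable fraction of
#' nuclei is laid out in touching clumps (centres closer than the sum of
#' the minor semi-axes); singlets are dart-thrown with a minimum
#' separation so they do not touch by accident.
#'
#' @param config A [simulation_config()].
#' @return A tibble (the ground-truth table), one row per nucleus, with
#'   geometry, `phase`, `dna_content`, `clump_id` (0 = singlet) and one
#'   `true_sum_<channel>` column per configured channel (integrated AU).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_cells
  if (n <= 0) stop("n_cells must be positive")
  set.seed(config$seed)
  im <- config$intensity_model

  phases <- names(config$fractions)
  counts <- as.vector(rmultinom(1, n, prob = as.numeric(config$fractions)))
  phase <- sample(rep(phases, counts))

  content <- draw_dna_content(phase, im)

  # geometry: equivalent radius scales mildly with DNA content
  ratio <- runif(n, config$axial_ratio_range[1], config$axial_ratio_range[2])
  radius <- config$mean_radius * content^(1/3) * rlnorm(n, 0, 0.05)
  a <- radius / sqrt(ratio)
  b <- radius * sqrt(ratio)
  theta <- runif(n, 0, pi)

  # clump assignment
  n_clumped <- round(config$clump_fraction * n)
  clump_id <- integer(n)
  if (n_clumped >= 2) {
    sizes <- integer(0)
    while (sum(sizes) < n_clumped - 1) {
      sizes <- c(sizes, sample(2:4, 1, prob = config$clump_size_probs))
    }
    if (sum(sizes) > n_clumped) sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_clumped)
    sizes <- sizes[sizes >= 2]
    members <- seq_len(sum(sizes))
    clump_id[members] <- rep(seq_along(sizes), sizes)
    clump_id <- sample(clump_id)  # random nuclei, not phase-linked
  }

  # placement: clump members chained at overlapping distance; singlets
  # dart-thrown with a minimum separation covering two of the largest
  # (G2, size-jittered) nuclei plus a smoothing margin, so nuclei only
  # ever touch when a clump asks them to
  nr <- config$shape[1]; nc <- config$shape[2]
  row <- numeric(n); col <- numeric(n)
  placed_r <- numeric(0); placed_c <- numeric(0)
  # separation covering two size-jittered G2 nuclei, capped by what the
  # requested density can actually accommodate
  min_sep <- min(3.25 * config$mean_radius, sqrt(0.35 * nr * nc / n))
  place_free <- function() {
    for (try in 1:50) {
      r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc)
      if (!length(placed_r) ||
          min((placed_r - r0)^2 + (placed_c - c0)^2) > min_sep^2)
        return(c(r0, c0))
    }
    c(r0, c0)  # crowded field: accept the last candidate
  }
  for (cid in setdiff(unique(clump_id), 0L)) {
    idx <- which(clump_id == cid)
    anchor <- place_free()
    row[idx[1]] <- anchor[1]; col[idx[1]] <- anchor[2]
    for (k in seq_along(idx)[-1]) {
      prev <- idx[k - 1]; cur <- idx[k]
      d <- config$overlap_factor * (b[prev] + b[cur])
      ang <- runif(1, 0, 2 * pi)
      row[cur] <- row[prev] + d * sin(ang)
      col[cur] <- col[prev] + d * cos(ang)
    }
    placed_r <- c(placed_r, mean(row[idx])); placed_c <- c(placed_c, mean(col[idx]))
  }
  for (i in which(clump_id == 0L)) {
    p <- place_free()
    row[i] <- p[1]; col[i] <- p[2]
    placed_r <- c(placed_r, p[1]); placed_c <- c(placed_c, p[2])
  }

  truth <- tibble(
    nucleus_id = seq_len(n), row = row, col = col,
    a = a, b = b, theta = theta,
    phase = phase, dna_content = content, clump_id = clump_id
  )

  # channel true integrated intensities (AU); mean-read channels (pHH3,
  # Ki67, marker) are specified as a per-pixel mean times ellipse area
  area <- pi * a * b
  for (ch in config$channels) {
    sum_ch <- switch(ch,
      dna = content * im$dna$g1_sum,
      edu = ifelse(phase == "S", rlnorm10(n, im$edu$pos), rlnorm10(n, im$edu$neg)),
      phh3 = area * ifelse(phase == "M", rlnorm10(n, im$phh3$pos),
                           rlnorm10(n, im$phh3$neg)),
      ki67 = area * ifelse(phase == "G0", rlnorm10(n, im$ki67$neg),
                           rlnorm10(n, im$ki67$pos)),
      marker = area * ifelse(phase %in% config$marker_positive_phases,
                             rlnorm10(n, im$marker$pos), rlnorm10(n, im$marker$neg))
    )
    truth[[paste0("true_sum_", ch)]] <- sum_ch
  }
  truth
}

gaussian_brush <- function(sigma) {
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
}

#' Render a field image from nucleus specifications
#'
#' Each nucleus is drawn as a filled ellipse (anti-aliased by 2x2 pixel
#' subsampling), convolved with a Gaussian PSF, and scaled so its rendered
#' integral equals its true integrated intensity in every channel.
#' Overlapping intensities add; ground-truth label-map pixels in overlaps
#' go to the nearer centre.  Background, radial illumination falloff,
#' Poisson shot noise and Gaussian read noise are applied per the config.
#'
#' @param specs Ground-truth tibble from [sample_population()] (any subset
#'   of rows; may be empty).
#' @param config A [simulation_config()].
#' @return List with `channels` (named list of matrices), `labels`
#'   (integer ground-truth label map) and `truth` (the input tibble with a
#'   logical `border` column flagging nuclei clipped by or touching the
#'   field edge).
#' @export
render_field <- function(specs, config) {
  stopifnot(inherits(config, "simulation_config"))
  # rendering noise gets its own stream derived from the config seed, so
  # render_field is bit-reproducible regardless of prior RNG state
  set.seed((config$seed %% 1500000000L) + 500009L)
  nr <- config$shape[1]; nc <- config$shape[2]
  chans <- lapply(config$channels, function(ch) matrix(0, nr, nc))
  names(chans) <- config$channels
  labels <- matrix(0L, nr, nc)
  if (nrow(specs) == 0) {
    return(list(channels = finish_field(chans, config),
                labels = labels, truth = cbind(specs, border = logical(0))))
  }
  best_d2 <- matrix(Inf, nr, nc)
  brush <- if (config$blur_sigma > 0) gaussian_brush(config$blur_sigma) else NULL
  pad <- if (is.null(brush)) 1L else (nrow(brush) %/% 2L) + 1L
  border <- logical(nrow(specs))

  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    ext <- max(s$a, s$b) + pad + 1
    r1 <- floor(s$row - ext); r2 <- ceiling(s$row + ext)
    c1 <- floor(s$col - ext); c2 <- ceiling(s$col + ext)
    rr <- r1:r2; cc <- c1:c2
    # anti-aliased ellipse coverage on the tile (2x2 subsampling)
    tile <- matrix(0, length(rr), length(cc))
    off <- c(-0.25, 0.25)
    ct <- cos(s$theta); st <- sin(s$theta)
    for (dr in off) for (dc in off) {
      ry <- rr + dr - s$row
      cx <- cc + dc - s$col
      u <- outer(ry, cx, function(y, x) (x * ct + y * st) / s$a)
      v <- outer(ry, cx, function(y, x) (-x * st + y * ct) / s$b)
      tile <- tile + (u * u + v * v <= 1) / 4
    }
    if (!is.null(brush)) {
      tile <- EBImage::filter2(tile, brush, boundary = 0)
      tile[tile < 0] <- 0
    }
    tsum <- sum(tile)
    if (tsum <= 0) next
    tile <- tile / tsum  # unit integral: channel sums are exact by construction

    # ground-truth mask: support of the rendered profile; a nucleus is
    # border-flagged when any support pixel lies on or beyond the edge
    supp <- which(tile > 0.02 * max(tile), arr.ind = TRUE)
    pr <- rr[supp[, 1]]; pc <- cc[supp[, 2]]
    border[i] <- any(pr <= 1L | pr >= nr | pc <= 1L | pc >= nc)

    keep_r <- rr >= 1 & rr <= nr
    keep_c <- cc >= 1 & cc <= nc
    tin <- tile[keep_r, keep_c, drop = FALSE]
    rin <- rr[keep_r]; cin <- cc[keep_c]
    if (!length(tin) || max(tin) <= 0) next  # entirely outside the field
    for (ch in config$channels) {
      chans[[ch]][rin, cin] <- chans[[ch]][rin, cin] +
        tin * s[[paste0("true_sum_", ch)]]
    }
    inside <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
    pr <- pr[inside]; pc <- pc[inside]
    d2 <- (pr - s$row)^2 + (pc - s$col)^2
    lin <- pr + (pc - 1L) * nr
    win <- d2 < best_d2[lin]
    labels[lin[win]] <- i
    best_d2[lin[win]] <- d2[win]
  }
  truth <- specs
  truth$border <- border
  list(channels = finish_field(chans, config), labels = labels, truth = truth)
}

# background, illumination falloff and noise
finish_field <- function(chans, config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  vignette <- NULL
  if (config$illumination_falloff > 0) {
    rr <- (seq_len(nr) - (nr + 1) / 2); cc <- (seq_len(nc) - (nc + 1) / 2)
    d2 <- outer(rr^2, cc^2, `+`)
    vignette <- 1 - config$illumination_falloff * d2 / max(d2)
  }
  lapply(chans, function(x) {
    x <- x + config$background
    if (!is.null(vignette)) x <- x * vignette
    if (config$poisson_noise) x <- matrix(rpois(length(x), x), nrow(x), ncol(x))
    if (config$read_noise_sd > 0) x <- x + rnorm(length(x), 0, config$read_noise_sd)
    x[x < 0] <- 0
    x
  })
}

#' Simulate one complete field
#'
#' Convenience wrapper: [sample_population()] then [render_field()] under
#' the config's seed (offset by `field_seed_offset` so wells and fields
#' differ deterministically).
#'
#' @inheritParams render_field
#' @param field_seed_offset Integer added to `config$seed` for this field.
#' @return As [render_field()].
#' @export
simulate_field <- function(config, field_seed_offset = 0L) {
  cfg <- config
  cfg$seed <- as.integer(config$seed + field_seed_offset)
  specs <- sample_population(cfg)
  render_field(specs, cfg)
}

#' Simulate EdU/BrdU dual-pulse labelling counts
#'
#' Models the dual-pulse experiment used to estimate S-phase duration:
#' cells uniformly distributed through an S phase of length `t_s` hours
#' are EdU-labelled, and after an interval `t` a second (BrdU) pulse marks
#' the cells still in S.  Exits are drawn per cell as Bernoulli with
#' probability `t / (t + t_s)`, which makes the ratio estimator
#' `deltaS = EdU+BrdU- / EdU+BrdU+` consistent for `t / t_s`, so
#' `T_s = t / deltaS` recovers `t_s`.  Cells entering S during the
#' interval appear as EdU-BrdU+ at the steady-state influx rate.
#'
#' @param t_s True S-phase duration, hours.
#' @param t Interval between the pulses, hours (must be < `t_s`).
#' @param n Number of EdU-positive (first-pulse) cells.
#' @param seed Integer seed.
#' @param s_fraction Fraction of the whole population in S phase, used to
#'   size the EdU-negative pool (for the %BrdU+ denominator).
#' @return One-row tibble of quadrant counts:
#'   `edu_pos_brdu_pos`, `edu_pos_brdu_neg`, `edu_neg_brdu_pos`,
#'   `edu_neg_brdu_neg`, and `n_total`.
#' @examples
#' simulate_dual_label_counts(t_s = 10.9, t = 2, n = 5000, seed = 1)
#' @export
simulate_dual_label_counts <- function(t_s, t, n, seed = 1L, s_fraction = 0.3) {
  if (n <= 0) stop("n must be positive")
  if (t <= 0 || t_s <= 0) stop("t and t_s must be positive")
  if (t >= t_s) stop("t must be smaller than t_s (only a minority may exit S)")
  if (s_fraction <= 0 || s_fraction >= 1) stop("s_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  exited <- rbinom(1, n, t / (t + t_s))
  n_neg <- round(n / s_fraction) - n
  entered <- rbinom(1, n_neg, min(1, (n * t / t_s) / n_neg))
  tibble(
    edu_pos_brdu_pos = n - exited,
    edu_pos_brdu_neg = exited,
    edu_neg_brdu_pos = entered,
    edu_neg_brdu_neg = n_neg - entered,
    n_total = n + n_neg
  )
}
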