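# Shared fixtures: analytic masks, tabular records from simulator ground
# truth, segmentation/ground-truth matching, and a cached training pool.

# binary disc/ellipse masks with pixel centres on the integer grid
disc_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xy <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(0L, n, n)
  m[(xy$row - ctr)^2 + (xy$col - ctr)^2 <= r^2] <- 1L
  m
}

ellipse_mask <- function(a, b, theta = 0, pad = 3) {
  n <- 2 * ceiling(max(a, b) + pad) + 1
  ctr <- (n + 1) / 2
  rowg <- matrix(1:n, n, n) - ctr
  colg <- matrix(1:n, n, n, byrow = TRUE) - ctr
  u <- (colg * cos(theta) + rowg * sin(theta)) / a
  v <- (-colg * sin(theta) + rowg * cos(theta)) / b
  m <- matrix(0L, n, n)
  m[u^2 + v^2 <= 1] <- 1L
  m
}

# per-cell record table straight from the simulator's ground truth
# (bypasses rendering; exact intensities, no measurement noise)
truth_to_records <- function(truth) {
  area <- pi * truth$a * truth$b
  rec <- tibble::tibble(nucleus_id = truth$nucleus_id,
                        dna_sum = truth$true_sum_dna)
  for (ch in c("edu", "phh3", "ki67", "marker")) {
    cn <- paste0("true_sum_", ch)
    if (cn %in% names(truth)) {
      rec[[paste0(ch, "_sum")]] <- truth[[cn]]
      rec[[paste0(ch, "_mean")]] <- truth[[cn]] / area
    }
  }
  rec
}

# greedy IoU matching between two label maps; returns per-truth best IoU
match_iou <- function(truth_labels, found_labels, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(truth_labels[truth_labels > 0]))
  vapply(ids, function(id) {
    mask <- truth_labels == id
    cand <- found_labels[mask]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    fmask <- found_labels == best
    sum(mask & fmask) / sum(mask | fmask)
  }, numeric(1))
}

# segmented objects with singlet/multiplet truth labels, pooled over
# clump-enriched fields; cached so classifier tests share one pool
segmented_training_pool <- local({
  cache <- NULL
  function(n_fields = 10, n_cells = 80, clump_fraction = 0.7, seed = 900) {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(n_cells = n_cells,
                             clump_fraction = clump_fraction, seed = seed)
    pool <- purrr::map_dfr(seq_len(n_fields), function(i) {
      fld <- simulate_field(cfg, field_seed_offset = i)
      lbl <- remove_border_objects(find_nuclei(fld$channels$dna, "B"))
      rec <- nucleus_features(fld$channels, lbl, well = "P1", field = i)
      dplyr::inner_join(rec, training_labels_from_truth(lbl, fld$truth),
                        by = "nucleus_id")
    })
    cache <<- pool
    pool
  }
})
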