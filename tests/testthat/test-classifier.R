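# Singlet/multiplet linear classifier: training, goodness, application.

toy_records <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    axial_ratio = c(rnorm(n, gap, 1), rnorm(n, 0, 1)),
    class = rep(c("singlet", "multiplet"), each = n)
  )
}

test_that("a margin-separated single feature trains to 100% accuracy", {
  rec <- toy_records(gap = 8)
  m <- train_singlet_classifier(rec, rec$class, features = "axial_ratio",
                                seed = 2)
  expect_equal(m$training_accuracy, 1)
  expect_gt(m$goodness, 3)
})

test_that("training validates its inputs", {
  rec <- toy_records()
  expect_error(train_singlet_classifier(rec, rep("singlet", nrow(rec)),
                                        features = "axial_ratio"),
               "both classes")
  few <- c(1:6, 61:66)  # both classes present, but fewer than 10 each
  expect_error(train_singlet_classifier(rec[few, ], rec$class[few],
                                        features = "axial_ratio"),
               "at least 10")
  rec$flat <- 1
  expect_warning(
    m <- train_singlet_classifier(rec, rec$class,
                                  features = c("axial_ratio", "flat"), seed = 1),
    "zero-variance")
  expect_equal(m$features, "axial_ratio")
})

test_that("training is deterministic given a seed", {
  pool <- segmented_training_pool()
  m1 <- train_singlet_classifier(pool, pool$class, seed = 7)
  m2 <- train_singlet_classifier(pool, pool$class, seed = 7)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
})

test_that("goodness is a d-prime: matches brute force and the closed form", {
  # identity model: score = standardised feature
  model <- structure(list(features = "axial_ratio",
                          weights = c(axial_ratio = 1), bias = 0,
                          center = c(axial_ratio = 0),
                          scale = c(axial_ratio = 1)),
                     class = "singlet_classifier")
  # two unit-variance populations 2.0 apart, n = 300: mean over seeds -> 2
  gs <- vapply(1:50, function(s) {
    rec <- toy_records(n = 150, gap = 2, seed = s)
    g <- classifier_goodness(model, rec, rec$class)
    # brute-force d-prime on the raw scores
    a <- rec$axial_ratio[rec$class == "singlet"]
    b <- rec$axial_ratio[rec$class == "multiplet"]
    pooled <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
    expect_equal(g, abs(mean(a) - mean(b)) / pooled)
    g
  }, numeric(1))
  expect_equal(mean(gs), 2.0, tolerance = 0.05)
  # identical class distributions -> 0
  rec0 <- toy_records(n = 100, gap = 0, seed = 3)
  expect_lt(classifier_goodness(model, rec0, rec0$class), 0.3)
  # degenerate: zero pooled SD
  recc <- tibble::tibble(axial_ratio = rep(1, 40),
                         class = rep(c("singlet", "multiplet"), 20))
  expect_warning(g <- classifier_goodness(model, recc, recc$class), "zero pooled")
  expect_identical(g, Inf)
})

test_that("goodness grows monotonically with the margin", {
  model <- structure(list(features = "axial_ratio",
                          weights = c(axial_ratio = 1), bias = 0,
                          center = c(axial_ratio = 0),
                          scale = c(axial_ratio = 1)),
                     class = "singlet_classifier")
  gs <- vapply(c(1, 3, 6), function(gap) {
    rec <- toy_records(n = 200, gap = gap, seed = 11)
    classifier_goodness(model, rec, rec$class)
  }, numeric(1))
  expect_true(all(diff(gs) > 0))
})

test_that("held-out accuracy reaches 95% at the 150+150 training scale", {
  pool <- segmented_training_pool()
  singlets <- which(pool$class == "singlet")
  multiplets <- which(pool$class == "multiplet")
  accs <- recalls <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    tr <- c(sample(singlets, 150), sample(multiplets, 150))
    te <- setdiff(seq_len(nrow(pool)), tr)
    # balanced held-out set so chance level is exactly 0.5
    te_s <- intersect(te, singlets); te_m <- intersect(te, multiplets)
    k <- min(length(te_s), length(te_m))
    te <- c(sample(te_s, k), sample(te_m, k))
    m <- train_singlet_classifier(pool[tr, ], pool$class[tr], seed = s)
    pred <- classify_singlets(pool[te, ], m)
    accs[s] <- mean(pred$singlet == (pool$class[te] == "singlet"))
    recalls[s] <- mean(!pred$singlet[pool$class[te] == "multiplet"])
  }
  expect_gte(mean(accs), 0.95)
  expect_gte(mean(recalls), 0.90)     # multiplet recall
})

test_that("shuffled training labels give chance-level held-out accuracy", {
  # with separable classes a single permutation can still align with the
  # true boundary by chance (accuracy near 0 or 1); the chance level is
  # the mean over many permutations, which is 0.5 by symmetry
  pool <- segmented_training_pool()
  singlets <- which(pool$class == "singlet")
  multiplets <- which(pool$class == "multiplet")
  set.seed(1)
  tr <- c(sample(singlets, 150), sample(multiplets, 150))
  te <- setdiff(seq_len(nrow(pool)), tr)
  te_s <- intersect(te, singlets); te_m <- intersect(te, multiplets)
  k <- min(length(te_s), length(te_m))
  te <- c(sample(te_s, k), sample(te_m, k))
  shuffled <- vapply(1:120, function(s) {
    set.seed(s)
    mshuf <- train_singlet_classifier(pool[tr, ], sample(pool$class[tr]),
                                      seed = s)
    mean(classify_singlets(pool[te, ], mshuf)$singlet ==
           (pool$class[te] == "singlet"))
  }, numeric(1))
  expect_gt(mean(shuffled), 0.40)
  expect_lt(mean(shuffled), 0.60)
})

test_that("classification is idempotent and handles degenerate inputs", {
  pool <- segmented_training_pool()
  m <- train_singlet_classifier(pool, pool$class, seed = 1)
  once <- classify_singlets(pool, m)
  twice <- classify_singlets(once, m)
  expect_identical(once$singlet, twice$singlet)
  empty <- classify_singlets(pool[0, ], m)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("singlet", "singlet_score") %in% names(empty)))
  m_inf <- m; m_inf$bias <- Inf
  expect_true(all(classify_singlets(pool, m_inf)$singlet))
  expect_error(classify_singlets(pool["area"], m), "lack classifier features")
})

test_that("singlet filtering cleans up the >2c tail of the DNA histogram", {
  cfg <- simulation_config(n_cells = 120, clump_fraction = 0.2, seed = 23)
  rec <- purrr::map_dfr(1:3, function(i) {
    fld <- simulate_field(cfg, field_seed_offset = i)
    lbl <- remove_border_objects(find_nuclei(fld$channels$dna, "B"))
    nucleus_features(fld$channels, lbl, well = "C1", field = i)
  })
  pool <- segmented_training_pool()
  m <- train_singlet_classifier(pool, pool$class, seed = 1)
  rec <- classify_singlets(rec, m)
  peak <- estimate_g1_peak(rec$dna_sum[rec$singlet], min_events = 100)
  rec <- normalise_dna(rec, peak)
  frac_all <- mean(rec$norm_dna > 2.5)
  frac_singlet <- mean(rec$norm_dna[rec$singlet] > 2.5)
  expect_lt(frac_singlet, frac_all)
})

test_that("classifier JSON serialisation round-trips", {
  pool <- segmented_training_pool()
  m <- train_singlet_classifier(pool, pool$class, seed = 5)
  path <- tempfile(fileext = ".json")
  write_classifier(m, path)
  m2 <- read_classifier(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$center, m$center)
  p1 <- classify_singlets(pool, m)
  p2 <- classify_singlets(pool, m2)
  expect_identical(p1$singlet, p2$singlet)
  td <- tidy(m)
  expect_equal(nrow(td), length(m$features) + 1)
  expect_s3_class(glance(m), "tbl_df")
})
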