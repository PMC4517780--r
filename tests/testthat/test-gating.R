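# G1-peak estimation, DNA normalisation, phase gating, subpopulations.

test_that("G1 peak is found in a bimodal mixture with G1 dominant", {
  set.seed(1)
  x <- c(rnorm(2000, 5000, 250), rnorm(1000, 10000, 500))
  p <- estimate_g1_peak(x)
  expect_equal(p, 5000, tolerance = 0.02)
})

test_that("a single peak is located to within 2%", {
  set.seed(2)
  x <- rnorm(3000, 1, 0.05)
  expect_equal(estimate_g1_peak(x), 1, tolerance = 0.02)
})

test_that("the lowest major mode wins even when G2 is taller", {
  set.seed(3)
  x <- c(rnorm(1600, 5000, 300), rnorm(2400, 10000, 300))
  expect_equal(estimate_g1_peak(x), 5000, tolerance = 0.02)
})

test_that("G1-peak estimation is scale-equivariant", {
  set.seed(4)
  x <- c(rnorm(1500, 5000, 250), rnorm(800, 10000, 500))
  p1 <- estimate_g1_peak(x)
  p2 <- estimate_g1_peak(x * 3.7)
  expect_equal(p2, 3.7 * p1, tolerance = 1e-8)
})

test_that("degenerate peak inputs are handled", {
  expect_error(estimate_g1_peak(numeric(0)), "no DNA values")
  expect_error(estimate_g1_peak(c(1, -2, 3), min_events = 1), "positive")
  expect_equal(suppressWarnings(estimate_g1_peak(rep(4200, 10))), 4200)
  expect_warning(estimate_g1_peak(rnorm(50, 5000, 10)), "unstable")
})

test_that("DNA normalisation is exact division", {
  rec <- tibble::tibble(dna_sum = c(5000, 10000, 2500))
  out <- normalise_dna(rec, 5000)
  expect_equal(out$norm_dna, c(1, 2, 0.5))
  expect_error(normalise_dna(rec, 0), "positive scalar")
  cfg <- simulation_config(n_cells = 2000, clump_fraction = 0, seed = 9)
  pop <- sample_population(cfg)
  rec2 <- truth_to_records(pop)
  out2 <- normalise_dna(rec2, estimate_g1_peak(rec2$dna_sum))
  med_g2 <- median(out2$norm_dna[pop$phase == "G2"])
  expect_gt(med_g2, 1.9); expect_lt(med_g2, 2.1)
})

test_that("log EdU is exact log10 with clamping of non-positives", {
  rec <- tibble::tibble(edu_sum = c(10^3.5, 1, 1000))
  expect_equal(log_edu(rec)$log_edu, c(3.5, 0, 3))
  rec0 <- tibble::tibble(edu_sum = c(100, 0, -5))
  expect_warning(out <- log_edu(rec0), "2 non-positive")
  expect_equal(attr(out, "n_clamped"), 2)
  expect_equal(out$log_edu[2], log10(10))  # clamped to min positive / 10
})

test_that("gate specs validate their intervals", {
  expect_error(gate_spec(list(G1 = list(norm_dna = c(2, 1)))), "low < high")
  expect_error(gate_spec(list(G1 = list(norm_dna = c(0, 1))), priority = "G2"),
               "permutation")
  expect_error(assign_phase(tibble::tibble(x = 1), gates_dna_only()),
               "missing feature")
})

test_that("paper-template gates classify canonical examples", {
  rec <- tibble::tibble(norm_dna = c(1.0, 0.5),
                        log_edu = c(3.5, 3.5),
                        phh3_mean = c(100, 100))
  out <- assign_phase(rec, gates_multiparametric())
  expect_equal(as.character(out$phase[1]), "G1")
  dna_only <- assign_phase(rec, gates_dna_only())
  expect_equal(as.character(dna_only$phase[2]), "subG1")
  # outside all gates -> unclassified, still counted
  odd <- tibble::tibble(norm_dna = 1.0, log_edu = 4.4, phh3_mean = 100)
  out2 <- assign_phase(odd, gates_multiparametric())
  expect_equal(as.character(out2$phase), "unclassified")
  dist <- phase_distribution(out2)
  expect_equal(sum(dist$fraction), 1)
  expect_equal(dist$count[dist$phase == "unclassified"], 1L)
})

test_that("boundary values belong to the upper gate exactly once", {
  cuts <- c(0.75, 1.25, 1.75, 2.5)
  rec <- tibble::tibble(norm_dna = cuts)
  out <- assign_phase(rec, gates_dna_only())
  expect_equal(as.character(out$phase), c("G1", "S", "G2/M", ">G2/M"))
  dist <- phase_distribution(out)
  expect_equal(sum(dist$count), 4L)
  expect_equal(sum(dist$fraction), 1)
})

test_that("Ki67 gating separates G0 from G1 and recovers a quiescent fraction", {
  rec <- tibble::tibble(norm_dna = c(1, 1), log_edu = c(3.5, 3.5),
                        phh3_mean = c(50, 50), ki67_mean = c(100, 500))
  out <- assign_g0(rec)
  expect_equal(as.character(out$phase), c("G0", "G1"))
  expect_error(assign_g0(rec["norm_dna"]), "ki67_mean")
  # simulated population with 40% true G0
  cfg <- simulation_config(
    n_cells = 4000, clump_fraction = 0,
    fractions = phase_fractions(G1 = 0.25, S = 0.2, G2 = 0.1, M = 0.05, G0 = 0.4),
    channels = c("dna", "edu", "phh3", "ki67"), seed = 27)
  pop <- sample_population(cfg)
  rec2 <- log_edu(truth_to_records(pop))
  rec2 <- normalise_dna(rec2, estimate_g1_peak(rec2$dna_sum))
  out2 <- assign_g0(rec2)
  g0 <- mean(out2$phase == "G0")
  expect_lt(abs(g0 - 0.4), 0.03)
})

test_that("phase fractions always sum to one, including unclassified", {
  cfg <- simulation_config(n_cells = 500, clump_fraction = 0, seed = 33)
  pop <- sample_population(cfg)
  rec <- normalise_dna(log_edu(truth_to_records(pop)), 5000)
  for (g in list(gates_dna_only(), gates_multiparametric())) {
    d <- phase_distribution(assign_phase(rec, g))
    expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(d$count), nrow(rec))
  }
})

test_that("marker subpopulation logic: identity, empty and constructed cases", {
  cfg <- simulation_config(
    n_cells = 1500, clump_fraction = 0,
    channels = c("dna", "edu", "phh3", "marker"),
    marker_positive_phases = "G2", seed = 41)
  pop <- sample_population(cfg)
  rec <- normalise_dna(log_edu(truth_to_records(pop)),
                       estimate_g1_peak(truth_to_records(pop)$dna_sum))
  full <- phase_distribution(assign_phase(rec, gates_multiparametric()))
  sub_all <- subpopulation_distribution(rec, bound = -Inf)
  expect_equal(sub_all$distribution$count, full$count)
  expect_equal(sub_all$fraction_positive, 1)
  sub_none <- subpopulation_distribution(rec, bound = Inf)
  expect_equal(sum(sub_none$distribution$count), 0L)
  expect_equal(sub_none$n_positive, 0L)
  # marker imposed only on G2 -> marker-positive distribution ~100% G2
  sub_g2 <- subpopulation_distribution(rec, bound = 300)
  fr <- sub_g2$distribution
  expect_gte(fr$fraction[fr$phase == "G2"], 0.95)
  expect_equal(sub_g2$fraction_positive, mean(pop$phase == "G2"),
               tolerance = 0.05)
})

test_that("proliferation index is the ratio of EdU-positive fractions", {
  ctrl <- tibble::tibble(log_edu = c(rep(5, 30), rep(3.7, 70)))
  expect_equal(proliferation_index(ctrl, ctrl)$proliferation_index, 1)
  none <- tibble::tibble(log_edu = rep(3.7, 50))
  expect_equal(proliferation_index(none, ctrl)$proliferation_index, 0)
  half <- tibble::tibble(log_edu = c(rep(5, 15), rep(3.7, 85)))
  expect_equal(proliferation_index(half, ctrl)$proliferation_index, 0.5)
  expect_error(proliferation_index(ctrl[0, ], ctrl), "non-empty")
})

test_that("the DNA histogram conserves counts in equal-width bins", {
  expect_equal(sum(dna_histogram(tibble::tibble(norm_dna = numeric(0)))$count), 0L)
  one <- dna_histogram(tibble::tibble(norm_dna = rep(1.001, 7)))
  expect_equal(sum(one$count > 0), 1L)
  expect_equal(sum(one$count), 7L)
  set.seed(5)
  rec <- tibble::tibble(norm_dna = runif(500, 0, 5))
  h <- dna_histogram(rec, bins = 300, max_dna = 4)
  expect_equal(nrow(h), 300)
  expect_equal(sum(h$count), sum(rec$norm_dna < 4))
})

test_that("gate specs round-trip through YAML", {
  spec <- gates_g0()
  path <- tempfile(fileext = ".yaml")
  gates_to_yaml(spec, path)
  spec2 <- gates_from_yaml(path)
  expect_equal(spec2$priority, spec$priority)
  expect_equal(spec2$gates, spec$gates)
  expect_equal(spec2$mode, spec$mode)
})
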