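test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 17, n_follows = 10)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$repertoires$present, b$repertoires$present)
  expect_identical(a$scans, b$scans)
  expect_identical(a$gestures, b$gestures)
  # a different seed changes the data
  c <- generate_dataset(synthetic_config(seed = 18, n_follows = 10))
  expect_false(identical(a$scans, c$scans))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(overlap_core = 1.2), "probabilities")
  expect_error(synthetic_config(scans_per_follow = 1), "scans per follow")
  expect_error(synthetic_config(n_individuals = 1), "at least 2")
  expect_error(synthetic_config(gesture_rate_per_follow = -1), "nonnegative")
  expect_error(synthetic_config(catalog_sizes = c(visual = 10, tactile = 5)),
               "all four modalities")
  # a positive core fraction that rounds to zero core types is rejected
  expect_error(generate_population(
    synthetic_config(overlap_core = 0.01,
                     catalog_sizes = c(visual = 30, tactile = 12,
                                       auditory_short = 8, auditory_long = 10))),
    "catalog too small")
})

test_that("full overlap gives identical repertoires and pairwise kappa 1", {
  pop <- generate_population(synthetic_config(seed = 2, overlap_core = 1))
  expect_true(all(pop$repertoires$present))
  K <- suppressMessages(kappa_matrix(pop$repertoires, "all"))
  off <- unclass(K)[row(K) != col(K)]
  # all repertoires identical; with every type present kappa is degenerate
  # over the full catalog, so check identity directly
  for (i in 2:nrow(pop$repertoires$present)) {
    expect_equal(pop$repertoires$present[i, ], pop$repertoires$present[1, ])
  }
  expect_true(all(is.na(off)))
})

test_that("zero core with disjoint individual types shares no gesture type", {
  pop <- generate_population(
    synthetic_config(seed = 3, overlap_core = 0, individual_type_mode = "disjoint"))
  pr <- pop$repertoires$present
  shared <- tcrossprod(pr * 1)
  diag(shared) <- 0
  expect_equal(sum(shared), 0)
})

test_that("mean pairwise kappa tracks the analytic expectation of the design", {
  # shared-pool design: fraction f of the catalog present in everyone, the
  # rest carried independently with probability q. The expected 2x2 table for
  # a dyad over a catalog of size m is a = f*m + (1-f)*m*q^2,
  # b = c = (1-f)*m*q*(1-q), d = (1-f)*m*(1-q)^2; kappa of that table is the
  # large-catalog expectation of the dyadic kappa.
  cfg <- synthetic_config(seed = 23)
  f <- cfg$overlap_core; q <- cfg$extra_type_prob
  m <- sum(cfg$catalog_sizes)
  a <- f * m + (1 - f) * m * q^2
  b <- (1 - f) * m * q * (1 - q)
  d <- (1 - f) * m * (1 - q)^2
  po <- (a + d) / m
  pe <- ((a + b)^2 + (d + b)^2) / m^2
  kappa_expected <- (po - pe) / (1 - pe)
  ks <- sapply(1:8, function(s) {
    pop <- generate_population(synthetic_config(seed = 100 + s))
    K <- suppressMessages(kappa_matrix(pop$repertoires, "all"))
    mean(unclass(K)[row(K) != col(K)], na.rm = TRUE)
  })
  expect_equal(mean(ks), kappa_expected, tolerance = 0.05)
  # monotonicity: more core overlap, higher mean kappa
  mean_k <- function(core, s) {
    pop <- generate_population(synthetic_config(seed = s, overlap_core = core))
    K <- suppressMessages(kappa_matrix(pop$repertoires, "all"))
    mean(unclass(K)[row(K) != col(K)], na.rm = TRUE)
  }
  lo <- mean(sapply(1:5, function(s) mean_k(0.2, 200 + s)))
  hi <- mean(sapply(1:5, function(s) mean_k(0.8, 200 + s)))
  expect_gt(hi, lo)
})

test_that("generated follows satisfy the scan and gesture file invariants", {
  cfg <- synthetic_config(seed = 29, n_follows = 20)
  ds <- generate_dataset(cfg)
  expect_silent(validate_scans(ds$scans, individuals = ds$individuals))
  expect_silent(validate_gestures(ds$gestures, individuals = ds$individuals))
  expect_equal(nrow(ds$scans), 20 * cfg$scans_per_follow)
  expect_true(all(table(ds$scans$follow_id) == cfg$scans_per_follow))
  # and they survive a CSV round-trip against the readers
  dir <- withr::local_tempdir()
  write_scans(ds$scans, file.path(dir, "s.csv"))
  write_gestures(ds$gestures, file.path(dir, "g.csv"))
  expect_equal(nrow(read_scans(file.path(dir, "s.csv"))), nrow(ds$scans))
  expect_equal(nrow(read_gestures(file.path(dir, "g.csv"))), nrow(ds$gestures))
})

test_that("a zero gesture rate yields scans but no gesture events", {
  ds <- generate_dataset(synthetic_config(seed = 31, n_follows = 6,
                                          gesture_rate_per_follow = 0))
  expect_equal(nrow(ds$gestures), 0L)
  expect_equal(nrow(ds$scans), 6 * 9)
})

test_that("a null bonding effect leaves kappa and proximity uncorrelated", {
  cors <- sapply(1:10, function(s) {
    ds <- generate_dataset(synthetic_config(seed = 400 + s, bonding_effect = 0,
                                            n_follows = 60))
    K <- suppressMessages(kappa_matrix(ds$repertoires, "all"))
    P <- bonding_matrix(ds$scans, "proximity", ids = ds$individuals$id)
    off <- row(P) != col(P)
    suppressWarnings(cor(unclass(P)[off],
                         unclass(K)[rownames(P), rownames(P)][off],
                         use = "complete.obs"))
  })
  expect_lt(abs(mean(cors)), 0.08)
})
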