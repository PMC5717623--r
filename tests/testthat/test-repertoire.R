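# Brute-force oracle for Cohen's kappa: cross-tabulate and use the textbook
# marginal formula, independently of the package's counting code.
oracle_kappa <- function(a, b) {
  tab <- table(factor(a, levels = c(FALSE, TRUE)),
               factor(b, levels = c(FALSE, TRUE)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

test_that("cohens_kappa matches the hand-derived contingency value", {
  # 2x2 table: both-present 4, only-A 1, only-B 1, both-absent 4 over n = 10
  a <- c(rep(TRUE, 5), rep(FALSE, 5))
  b <- c(rep(TRUE, 4), FALSE, TRUE, rep(FALSE, 4))
  expect_equal(cohens_kappa(a, b), 0.6)
  expect_equal(oracle_kappa(a, b), 0.6)
})

test_that("kappa is symmetric, bounded, 1 on self, and NA when degenerate", {
  set.seed(11)
  for (rep in 1:50) {
    a <- runif(8) < 0.5
    b <- runif(8) < 0.5
    k <- cohens_kappa(a, b)
    expect_equal(k, cohens_kappa(b, a))
    if (!is.na(k)) expect_true(k >= -1 - 1e-12 && k <= 1 + 1e-12)
    if (length(unique(a)) > 1) expect_equal(cohens_kappa(a, a), 1)
  }
  expect_true(is.na(cohens_kappa(rep(TRUE, 4), rep(TRUE, 4))))
  expect_error(cohens_kappa(c(TRUE, FALSE), TRUE), "same length")
  expect_error(cohens_kappa(logical(0), logical(0)), "non-empty")
})

test_that("intentionality filter retains types strictly above the 60% threshold", {
  crit <- data.frame(gesture_type = c("a", "b", "c", "d"),
                     n_intentional = c(61, 60, 10, 0),
                     n_total = c(100, 100, 100, 0),
                     stringsAsFactors = FALSE)
  expect_message(kept <- intentionality_filter(crit), "zero scored")
  expect_equal(kept, "a")  # 0.61 in, 0.60 exactly out, 0.10 out, 0/0 excluded
  kept_ge <- suppressMessages(intentionality_filter(crit, strict = FALSE))
  expect_equal(kept_ge, c("a", "b"))
})

test_that("repertoires contain only types signalled towards adults", {
  g <- make_gestures()
  g <- rbind(g, g[1, ])
  g$event_id[5] <- "e05"
  g$recipient_id[5] <- "JUV"   # juvenile recipient: must not contribute
  g$gesture_type[5] <- "throw"
  g$modality[5] <- "auditory_long"
  adults <- c("AA", "BC", "CD", "DE")
  reps <- build_repertoires(g, adults)
  expect_equal(sort(names(which(reps$present["AA", ]))),
               sort(c("arm_beckon", "stomp")))
  expect_false("throw" %in% names(which(reps$present["AA", ])))
  # individual with no events -> empty repertoire
  expect_equal(sum(reps$present["DE", ]), 0L)
  # one event of one type -> singleton repertoire
  expect_equal(names(which(reps$present["BC", ])), "slap_object")
})

test_that("dyadic summary reproduces the asymmetric non-overlap worked example", {
  catalog <- simple_catalog(12)
  # |A \ B| = 5, |B \ A| = 2, shared 3
  reps <- make_repertoire_set(list(
    BB = sprintf("g%02d", 1:8),        # 5 unique (g01-g05) + 3 shared
    HW = sprintf("g%02d", 6:10)        # 3 shared (g06-g08) + 2 unique
  ), catalog)
  s_ab <- dyad_repertoire_summary(reps, "BB", "HW")
  s_ba <- dyad_repertoire_summary(reps, "HW", "BB")
  expect_equal(s_ab$heterog_size, 7)
  expect_equal(s_ba$heterog_size, 7)
  expect_equal(s_ab$homog_size, 3)
  expect_equal(s_ab$homog_size, s_ba$homog_size)
  # identity |A intersect B| + |A delta B| = |A union B|
  expect_equal(s_ab$homog_size + s_ab$heterog_size, 10)
})

test_that("per-modality kappa uses the per-modality catalog only", {
  catalog <- rbind(
    data.frame(gesture_type = c("v1", "v2", "v3", "v4"), modality = "visual"),
    data.frame(gesture_type = c("t1", "t2"), modality = "tactile")
  )
  reps <- make_repertoire_set(list(
    A = c("v1", "v2", "t1"),
    B = c("v1", "v2", "t2")
  ), catalog)
  # visual vectors agree fully and are non-constant within the visual catalog
  expect_equal(dyad_repertoire_summary(reps, "A", "B", "visual")$kappa, 1)
  # tactile vectors are exact complements over a 2-type catalog
  expect_equal(dyad_repertoire_summary(reps, "A", "B", "tactile")$kappa, -1)
  # overall kappa differs from both (computed over the full 6-type catalog)
  k_all <- dyad_repertoire_summary(reps, "A", "B", "all")$kappa
  expect_true(k_all < 1 && k_all > -1)
})

test_that("kappa and size matrices are symmetric with missing diagonal", {
  catalog <- simple_catalog(8)
  reps <- make_repertoire_set(list(
    A = c("g01", "g02"), B = c("g01", "g03"), C = c("g04")
  ), catalog)
  K <- kappa_matrix(reps)
  expect_false(attr(K, "directed"))
  expect_equal(unclass(K), t(unclass(K)))
  expect_true(all(is.na(diag(K))))
  H <- repertoire_size_matrix(reps, "heterogeneous")
  expect_equal(H["A", "B"], 2)
  expect_equal(H["B", "A"], 2)
  expect_equal(repertoire_size_matrix(reps, "homogeneous")["A", "B"], 1)
})

test_that("sequence gesture types are classified against both repertoires", {
  catalog <- simple_catalog(10)
  reps <- make_repertoire_set(list(
    S = sprintf("g%02d", 1:5),
    R = sprintf("g%02d", 3:7),
    E = character(0)
  ), catalog)
  seq_ev <- data.frame(
    sequence_id = "s1", signaller_id = "S", recipient_id = "R",
    gesture_type = sprintf("g%02d", 1:5), stringsAsFactors = FALSE)
  cls <- classify_sequence(seq_ev, reps)
  # five distinct types, three shared (g03-g05), two unique to the signaller
  expect_equal(cls$homog_repertoire_size, 3)
  expect_equal(cls$heterog_repertoire_size, 2)
  expect_equal(sum(cls$homog_repertoire_size, cls$heterog_repertoire_size),
               length(unique(seq_ev$gesture_type)))
  # all shared -> zero heterogeneous
  seq2 <- seq_ev[3:5, ]
  expect_equal(classify_sequence(seq2, reps)$heterog_repertoire_size, 0)
  # single unshared type -> (0, 1)
  seq3 <- seq_ev[1, ]
  cls3 <- classify_sequence(seq3, reps)
  expect_equal(cls3$homog_repertoire_size, 0)
  expect_equal(cls3$heterog_repertoire_size, 1)
  # recipient with no observed repertoire -> flagged, sizes missing
  seq4 <- seq_ev
  seq4$recipient_id <- "E"
  expect_message(cls4 <- classify_sequence(seq4, reps), "flagged")
  expect_true(cls4$flagged)
  expect_true(is.na(cls4$homog_repertoire_size))
})
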