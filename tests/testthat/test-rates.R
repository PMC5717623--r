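# Scans where AA is focal for a controlled rate example: j in party for all
# rows, behaviour conditions met in a known subset.
make_rate_scans <- function() {
  n <- 10
  sc <- data.frame(
    follow_id = rep(c("F1", "F2"), each = 5),
    focal_id = "AA",
    scan_index = rep(1:5, 2),
    nn_id = c("BC", "BC", "BC", "CD", NA, "BC", "BC", "BC", "BC", "BC"),
    nn_distance_m = c(1, 1.5, 3, 1, NA, 0.5, 1, 8, 1.2, 1.9),
    attention_present = c(TRUE, FALSE, TRUE, TRUE, NA, TRUE, TRUE, FALSE, FALSE, TRUE),
    focal_activity = c("feed", "feed", "feed", "feed", "rest",
                       "groom_give", "feed", "feed", "rest", "feed"),
    nn_activity = c("feed", "rest", "feed", "feed", NA,
                    "groom_receive", "feed", "feed", "rest", "feed"),
    stringsAsFactors = FALSE
  )
  sc$within_10m_ids <- I(rep(list(c("BC", "CD")), n))
  sc$party_ids <- I(rep(list(c("AA", "BC", "CD")), n))
  sc
}

test_that("bonding rates implement 60 * count ratio with nesting conditions", {
  sc <- make_rate_scans()
  expect_equal(co_party_scans(sc, "AA", "BC"), 10)
  expect_equal(co_party_scans(sc, "AA", "ZZ"), 0)
  # proximity: BC nearest neighbour within 2 m in rows 1, 2, 6, 7, 9, 10
  expect_equal(bonding_rate(sc, "AA", "BC", "proximity"), 60 * 6 / 10)
  # joint feeding additionally requires both feeding: rows 1, 7, 10
  expect_equal(bonding_rate(sc, "AA", "BC", "joint_feed"), 60 * 3 / 10)
  # grooming read from the focal's activity code towards its nearest neighbour
  expect_equal(bonding_rate(sc, "AA", "BC", "groom_given"), 60 * 1 / 10)
  expect_equal(bonding_rate(sc, "AA", "BC", "groom_received"), 0)
  # never co-present -> missing; zero hits with co-presence -> 0
  expect_true(is.na(bonding_rate(sc, "AA", "ZZ", "proximity")))
  expect_equal(bonding_rate(sc, "AA", "CD", "groom_mutual"), 0)
  expect_error(bonding_rate(sc, "AA", "BC", "hugging"), "unknown behaviour")
})

test_that("worked rate arithmetic: 6 behaviour scans over 30 party scans is 12 min/h", {
  n <- 30
  sc <- data.frame(
    follow_id = rep(sprintf("F%d", 1:6), each = 5),
    focal_id = "AA",
    scan_index = rep(1:5, 6),
    nn_id = "BC",
    nn_distance_m = c(rep(1, 6), rep(5, n - 6)),  # exactly 6 scans within 2 m
    attention_present = TRUE,
    focal_activity = "rest",
    nn_activity = "rest",
    stringsAsFactors = FALSE
  )
  sc$within_10m_ids <- I(rep(list("BC"), n))
  sc$party_ids <- I(rep(list(c("AA", "BC")), n))
  expect_equal(co_party_scans(sc, "AA", "BC"), 30)
  expect_equal(bonding_rate(sc, "AA", "BC", "proximity"), 12)
})

test_that("rates are bounded, nested under proximity, and order-invariant", {
  ds <- generate_dataset(synthetic_config(seed = 3, n_follows = 30))
  ids <- ds$individuals$id
  tab <- bonding_rate_table(ds$scans, ids = ids)
  ok <- !is.na(tab$minutes_per_hour)
  expect_true(all(tab$minutes_per_hour[ok] >= 0 & tab$minutes_per_hour[ok] <= 60))
  prox <- tab[tab$behaviour == "proximity", ]
  for (b in c("joint_feed", "joint_rest", "joint_travel",
              "attention_present", "attention_absent")) {
    sub <- tab[tab$behaviour == b, ]
    both <- !is.na(sub$minutes_per_hour) & !is.na(prox$minutes_per_hour)
    expect_true(all(sub$minutes_per_hour[both] <= prox$minutes_per_hour[both] + 1e-9),
                info = b)
  }
  shuffled <- ds$scans[rev(seq_len(nrow(ds$scans))), ]
  expect_equal(bonding_rate(shuffled, ids[1], ids[2], "proximity"),
               bonding_rate(ds$scans, ids[1], ids[2], "proximity"))
})

# Exhaustive enumeration oracle: distribution of the signed-rank statistic
# over all 2^N sign assignments of the observed absolute ranks.
oracle_signed_rank <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  t_obs <- min(w_pos, sum(r) - w_pos)
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  S <- sum(r)
  p <- mean(w_all <= t_obs + 1e-9 | w_all >= S - t_obs - 1e-9)
  list(T = t_obs, N = n, p = p)
}

test_that("signed-rank test matches exhaustive enumeration on small samples", {
  x <- c(1, 3, 4, 5)
  y <- c(2, 1, 6, 2)
  got <- signed_rank_test(x, y)
  want <- oracle_signed_rank(x, y)
  expect_equal(got$T, want$T)
  expect_equal(got$N, want$N)
  expect_equal(got$p, want$p)
  set.seed(21)
  for (rep in 1:20) {
    x <- sample(0:6, 8, replace = TRUE)
    y <- sample(0:6, 8, replace = TRUE)
    if (all(x == y)) next
    got <- signed_rank_test(x, y)
    want <- oracle_signed_rank(x, y)
    expect_equal(got$p, want$p, info = paste("rep", rep))
    expect_equal(got$T, want$T, info = paste("rep", rep))
  }
  # all differences zero -> reported as not applicable
  res <- signed_rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_false(res$applicable)
  expect_equal(res$N, 0L)
  expect_true(is.na(res$p))
})

test_that("scan-independence check pairs counts at the named scan positions", {
  ds <- generate_dataset(synthetic_config(seed = 5, n_follows = 24))
  out <- scan_independence_check(ds$scans)
  expect_equal(nrow(out), 4)
  expect_setequal(out$measure, c("within_10m", "party"))
  expect_true(all(out$N[out$applicable] > 0))
  expect_true(all(out$p[out$applicable] > 0 & out$p[out$applicable] <= 1))
  # duplicating every follow doubles the counts but preserves the ranks of
  # the paired differences, so the statistic is unchanged
  sc2 <- ds$scans
  sc2$follow_id <- paste0(sc2$follow_id, "b")
  out2 <- scan_independence_check(rbind(ds$scans, sc2))
  expect_equal(out2$T, out$T)
  expect_error(scan_independence_check(ds$scans[ds$scans$scan_index == 1, ]),
               "no complete follow")
})
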