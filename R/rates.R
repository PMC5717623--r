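# Dyadic bonding rates from scan records, and the scan-independence check.
#
# Each instantaneous scan stands for one scan interval (default 2 min) of
# observation, so for a dyad (i focal, j partner) the rate of a behaviour is
#   minutes_per_hour = 60 * n_behaviour / n_party,
# where n_party counts the scans of i's follows in which j was in i's party
# and n_behaviour counts those scans in which the behaviour's condition held.
# The interval length cancels. The rate is missing when the dyad was never
# co-present in a party.

# Logical vector over i's scans: does the behaviour condition hold w.r.t. j?
.behaviour_hit <- function(sc, j, behaviour) {
  nn_j <- !is.na(sc$nn_id) & sc$nn_id == j
  within2 <- nn_j & !is.na(sc$nn_distance_m) & sc$nn_distance_m <= 2
  act <- function(x, a) !is.na(x) & x == a
  switch(behaviour,
    proximity = within2,
    joint_feed = within2 & act(sc$focal_activity, "feed") & act(sc$nn_activity, "feed"),
    joint_rest = within2 & act(sc$focal_activity, "rest") & act(sc$nn_activity, "rest"),
    joint_travel = within2 & act(sc$focal_activity, "travel") & act(sc$nn_activity, "travel"),
    attention_present = within2 & !is.na(sc$attention_present) & sc$attention_present,
    attention_absent = within2 & !is.na(sc$attention_present) & !sc$attention_present,
    groom_given = nn_j & act(sc$focal_activity, "groom_give"),
    groom_received = nn_j & act(sc$focal_activity, "groom_receive"),
    groom_mutual = nn_j & act(sc$focal_activity, "groom_mutual"),
    stop(sprintf("unknown behaviour '%s'", behaviour), call. = FALSE)
  )
}

#' Number of scans a partner spent in the focal's party
#'
#' @param scans scan table ([read_scans()]).
#' @param i focal individual.
#' @param j partner.
#' @return count of scans with `i` focal and `j` in `party_ids`.
#' @export
co_party_scans <- function(scans, i, j) {
  sc <- scans[scans$focal_id == i, ]
  sum(vapply(sc$party_ids, function(p) j %in% p, logical(1)))
}

#' Dyadic bonding rate for one behaviour
#'
#' Duration of a bonding behaviour between focal `i` and partner `j`, in
#' minutes per hour the pair spent in the same party, computed from `i`'s
#' focal follows only (rates are directed; `i -> j` and `j -> i` are
#' computed from different follows). The joint-activity and attention
#' behaviours require `j` to be the nearest neighbour within 2 m with the
#' matching activity or attention state; grooming is read from the focal's
#' activity code towards its nearest neighbour (`groom_given` means the
#' focal grooms `j`); `proximity` requires only nearest-neighbour status
#' within 2 m.
#'
#' @param scans scan table.
#' @param i focal individual.
#' @param j partner.
#' @param behaviour one of `joint_feed`, `joint_rest`, `joint_travel`,
#'   `groom_given`, `groom_received`, `groom_mutual`, `attention_present`,
#'   `attention_absent`, `proximity`.
#' @return minutes per hour in `[0, 60]`, or `NA` when the dyad was never
#'   co-present in a party.
#' @export
bonding_rate <- function(scans, i, j, behaviour) {
  if (!behaviour %in% BONDING_BEHAVIOURS) {
    stop(sprintf("unknown behaviour '%s'", behaviour), call. = FALSE)
  }
  sc <- scans[scans$focal_id == i, ]
  in_party <- vapply(sc$party_ids, function(p) j %in% p, logical(1))
  n_party <- sum(in_party)
  if (n_party == 0) return(NA_real_)
  n_beh <- sum(.behaviour_hit(sc, j, behaviour) & in_party)
  60 * n_beh / n_party
}

#' Long-format bonding rates for all ordered dyads
#'
#' @param scans scan table.
#' @param ids individuals to enumerate (default: all focal ids observed).
#' @param behaviours behaviours to compute (default all nine).
#' @return `data.frame` with columns `id_a` (focal), `id_b` (partner),
#'   `behaviour`, `minutes_per_hour`.
#' @export
bonding_rate_table <- function(scans, ids = sort(unique(scans$focal_id)),
                               behaviours = BONDING_BEHAVIOURS) {
  rows <- list()
  for (b in behaviours) {
    for (i in ids) for (j in ids) {
      if (i == j) next
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = i, id_b = j, behaviour = b,
        minutes_per_hour = bonding_rate(scans, i, j, b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Directed bonding-rate network for one behaviour
#'
#' @param scans scan table.
#' @param behaviour one of the nine bonding behaviours.
#' @param ids node set (default: all focal ids observed).
#' @return a directed [dyad_matrix()] of minutes-per-hour rates; cell
#'   `[i, j]` is the rate directed by focal `i` towards `j`.
#' @export
bonding_matrix <- function(scans, behaviour, ids = sort(unique(scans$focal_id))) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    if (i == j) next
    m[i, j] <- bonding_rate(scans, i, j, behaviour)
  }
  as_dyad_matrix(m, directed = TRUE)
}

# Exact two-tailed signed-rank p-value by generating-function convolution
# over the (tie-averaged) ranks; doubling the ranks makes them integers.
.signed_rank_exact_p <- function(r, w_obs) {
  w2 <- as.integer(round(2 * r))
  M <- sum(w2)
  f <- numeric(M + 1)
  f[1] <- 1
  for (w in w2) f <- f + c(numeric(w), f[seq_len(M + 1 - w)])
  f <- f / 2^length(w2)
  t2 <- as.integer(round(2 * w_obs))
  lo <- sum(f[seq_len(t2 + 1)])                  # P(2W+ <= 2T)
  hi <- sum(f[(M - t2 + 1):(M + 1)])             # P(2W+ >= 2(S - T))
  min(1, lo + hi)
}

#' Wilcoxon signed-rank test on paired dyadic counts
#'
#' Paired two-tailed signed-rank test. Zero differences are dropped; ties in
#' the absolute differences get average ranks. The reported statistic `T` is
#' the smaller of the positive- and negative-rank sums. For `N <= 100`
#' non-zero pairs the p-value is exact (distribution of the rank sum built
#' by convolution over the rank weights, which handles ties); beyond that a
#' normal approximation with tie correction is used.
#'
#' @param x,y paired count vectors.
#' @return list with `T`, `N` (non-zero differences), `p`, `method`, and
#'   `applicable` (`FALSE` when all differences are zero, in which case the
#'   test is reported as not applicable with `T` and `p` missing).
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length", call. = FALSE)
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(T = NA_real_, N = 0L, p = NA_real_, method = "none",
                applicable = FALSE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  t_obs <- min(w_pos, w_neg)
  if (n <= 100) {
    p <- .signed_rank_exact_p(r, t_obs)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(T = t_obs, N = n, p = p, method = method, applicable = TRUE)
}

#' Scan-independence quality check
#'
#' Tests whether association counts at different scan positions of a follow
#' can be treated as exchangeable, by pairing, for every (focal, partner)
#' dyad, the number of scans at position `a` versus position `b` (across all
#' of that focal's follows) in which the partner was within 10 m of the
#' focal, or in the focal's party, and applying a Wilcoxon signed-rank test.
#' By default the first scan is compared against the second (adjacent) and
#' against the last (follow-length separation) for both measures.
#'
#' @param scans scan table with at least one complete follow covering the
#'   requested scan positions.
#' @param scan_pairs list of length-2 integer vectors of scan positions to
#'   compare.
#' @param measures `"within_10m"`, `"party"`, or both.
#' @param ids id universe for partners (default: everyone seen in the scans).
#' @return `data.frame` with one row per measure and scan pair: `measure`,
#'   `scan_a`, `scan_b`, `T`, `N`, `p`, `applicable`.
#' @export
scan_independence_check <- function(scans,
                                    scan_pairs = list(c(1L, 2L), c(1L, 9L)),
                                    measures = c("within_10m", "party"),
                                    ids = NULL) {
  if (is.null(ids)) {
    ids <- sort(unique(c(scans$focal_id, unlist(scans$party_ids))))
  }
  positions <- sort(unique(unlist(scan_pairs)))
  focals <- unique(scans$focal_id)
  complete <- vapply(split(scans$scan_index, scans$follow_id),
                     function(s) all(positions %in% s), logical(1))
  if (!any(complete)) {
    stop("no complete follow covers the requested scan positions", call. = FALSE)
  }
  count_at <- function(measure, pos) {
    sc <- scans[scans$scan_index == pos, ]
    sets <- if (measure == "within_10m") sc$within_10m_ids else sc$party_ids
    out <- matrix(0L, length(focals), length(ids), dimnames = list(focals, ids))
    for (k in seq_len(nrow(sc))) {
      f <- sc$focal_id[k]
      hit <- intersect(sets[[k]], ids)
      out[f, hit] <- out[f, hit] + 1L
    }
    out
  }
  rows <- list()
  for (m in measures) {
    for (pair in scan_pairs) {
      xa <- count_at(m, pair[1])
      xb <- count_at(m, pair[2])
      keep <- outer(focals, ids, FUN = "!=")
      res <- signed_rank_test(xa[keep], xb[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, scan_a = pair[1], scan_b = pair[2],
        T = res$T, N = res$N, p = res$p, applicable = res$applicable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
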