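# Synthetic focal-follow data with the statistical structure the analysis
# assumes: a 12-adult fission-fusion community, per-modality gesture
# repertoires built from a group-wide core plus individual-specific types,
# focal follows of nine 2-min scans, and a tunable coupling between dyadic
# repertoire agreement (Cohen's kappa) and the per-scan probability of close
# (<= 2 m) proximity — the planted effect every downstream inference stage
# is validated against.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the study design the package targets: 12 adults (six
#' male, six female), focal follows of nine scans at 2-min intervals, four
#' gesture modalities with catalog sizes 30 (visual), 12 (tactile),
#' 8 (short-range auditory) and 10 (long-range auditory), and roughly 4.5
#' gesture sequences per follow so that 120 follows yield on the order of
#' 550 sequences.
#'
#' `bonding_effect` is the logit-scale coefficient coupling standardized
#' dyadic kappa to the per-scan probability that the partner is the focal's
#' nearest neighbour within 2 m; the default (0.65) is calibrated so that the
#' realized standardized dyadic effect of kappa on the proximity rate is
#' about 0.5 under the default design (see the methods vignette). Set it to
#' 0 for a null coupling.
#'
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param n_individuals number of adults (males first half, females second).
#' @param catalog_sizes named counts of gesture types per modality.
#' @param overlap_core fraction of each modality catalog shared group-wide.
#' @param individual_type_mode how non-core types are assigned:
#'   `"shared_pool"` (each individual carries each non-core type
#'   independently with probability `extra_type_prob`, so non-core types can
#'   be shared by chance) or `"disjoint"` (the non-core pool is partitioned,
#'   giving each individual types no one else has).
#' @param extra_type_prob per-type carry probability in shared-pool mode.
#' @param dyad_overlap_sd standard deviation of the stable dyad-specific
#'   logit deviation in party co-membership (fission-fusion preference
#'   noise).
#' @param n_follows number of 18-min focal follows (focals rotate).
#' @param scans_per_follow scans per follow.
#' @param scan_interval_min minutes between scans.
#' @param bonding_effect see above.
#' @param party_prob baseline probability a given other adult is in the
#'   focal's party during a follow.
#' @param within_10m_prob per-scan probability a party member is within 10 m.
#' @param proximity_base baseline logit of nearest-neighbour-within-2-m
#'   status per scan.
#' @param emotional_response_prob_homog probability a responded-to
#'   homogeneous gesture draws an emotional (rather than goal-directed)
#'   response.
#' @param goal_response_prob_heterog probability a responded-to
#'   heterogeneous gesture draws a goal-directed response.
#' @param gesture_rate_per_follow expected gesture events per follow.
#' @param panthoot_prob probability a gesture is accompanied by a panthoot.
#' @param n_kin_pairs number of maternal kin pairs to plant.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_individuals = 12L,
                             catalog_sizes = c(visual = 30L, tactile = 12L,
                                               auditory_short = 8L,
                                               auditory_long = 10L),
                             overlap_core = 0.5,
                             individual_type_mode = c("shared_pool", "disjoint"),
                             extra_type_prob = 0.35,
                             dyad_overlap_sd = 0.8,
                             n_follows = 120L,
                             scans_per_follow = 9L,
                             scan_interval_min = 2,
                             bonding_effect = 0.65,
                             party_prob = 0.7,
                             within_10m_prob = 0.6,
                             proximity_base = -1.0,
                             emotional_response_prob_homog = 0.60,
                             goal_response_prob_heterog = 0.60,
                             gesture_rate_per_follow = 4.5,
                             panthoot_prob = 0.05,
                             n_kin_pairs = 2L) {
  individual_type_mode <- match.arg(individual_type_mode)
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              catalog_sizes = catalog_sizes, overlap_core = overlap_core,
              individual_type_mode = individual_type_mode,
              extra_type_prob = extra_type_prob, dyad_overlap_sd = dyad_overlap_sd,
              n_follows = as.integer(n_follows),
              scans_per_follow = as.integer(scans_per_follow),
              scan_interval_min = scan_interval_min,
              bonding_effect = bonding_effect, party_prob = party_prob,
              within_10m_prob = within_10m_prob, proximity_base = proximity_base,
              emotional_response_prob_homog = emotional_response_prob_homog,
              goal_response_prob_heterog = goal_response_prob_heterog,
              gesture_rate_per_follow = gesture_rate_per_follow,
              panthoot_prob = panthoot_prob, n_kin_pairs = as.integer(n_kin_pairs))
  probs <- c(overlap_core = overlap_core, extra_type_prob = extra_type_prob,
             party_prob = party_prob, within_10m_prob = within_10m_prob,
             emotional_response_prob_homog = emotional_response_prob_homog,
             goal_response_prob_heterog = goal_response_prob_heterog,
             panthoot_prob = panthoot_prob)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop(sprintf("probabilities must lie in [0, 1]: %s",
                 paste(names(probs)[bad], collapse = ", ")), call. = FALSE)
  }
  if (cfg$n_individuals < 2) stop("need at least 2 individuals", call. = FALSE)
  if (any(catalog_sizes < 1)) stop("catalog sizes must be >= 1", call. = FALSE)
  if (!setequal(names(catalog_sizes), GESTURE_MODALITIES)) {
    stop("catalog_sizes must name all four modalities", call. = FALSE)
  }
  if (cfg$scans_per_follow < 2) stop("need at least 2 scans per follow", call. = FALSE)
  if (cfg$n_follows < 1) stop("need at least 1 follow", call. = FALSE)
  if (dyad_overlap_sd < 0) stop("dyad_overlap_sd must be nonnegative", call. = FALSE)
  if (gesture_rate_per_follow < 0) stop("gesture_rate_per_follow must be nonnegative", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic population
#'
#' Draws individuals (ids, sex, birth years, female reproductive status,
#' pantgrunt degrees concentrated in males so a dominance order exists),
#' maternal kin pairs, and per-modality gesture repertoires. Each modality
#' repertoire is the group-wide core (the first `round(overlap_core * size)`
#' types of the catalog, shared by everyone) plus individual-specific types
#' from the remainder of the catalog; `overlap_core = 1` makes all
#' repertoires identical (all pairwise kappa 1). Deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `individuals`, `kin_pairs`, `repertoires` (a
#'   `repertoire_set` of the true repertoires), `catalog`.
#' @export
generate_population <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("IND%02d", seq_len(n))
  n_male <- n %/% 2
  sex <- c(rep("male", n_male), rep("female", n - n_male))
  birth_year <- sample(1960:1995, n, replace = TRUE)
  status <- ifelse(sex == "male", "not_applicable",
                   sample(c("cycling", "pregnant", "nursing", "oestrous"),
                          n, replace = TRUE))
  indeg <- ifelse(sex == "male", round(rexp(n, rate = 1), 3), 0)
  outdeg <- round(runif(n, 0, 0.7), 3)
  individuals <- data.frame(id = ids, sex = sex, birth_year = birth_year,
                            reproductive_status = status,
                            pantgrunt_indegree = indeg,
                            pantgrunt_outdegree = outdeg,
                            stringsAsFactors = FALSE)
  kin_pairs <- data.frame(id_a = character(0), id_b = character(0),
                          stringsAsFactors = FALSE)
  if (config$n_kin_pairs > 0) {
    all_pairs <- t(utils::combn(ids, 2))
    pick <- sample.int(nrow(all_pairs), min(config$n_kin_pairs, nrow(all_pairs)))
    kin_pairs <- data.frame(id_a = all_pairs[pick, 1], id_b = all_pairs[pick, 2],
                            stringsAsFactors = FALSE)
  }
  catalog <- do.call(rbind, lapply(GESTURE_MODALITIES, function(m) {
    data.frame(gesture_type = sprintf("%s_%02d", m, seq_len(config$catalog_sizes[[m]])),
               modality = m, stringsAsFactors = FALSE)
  }))
  present <- matrix(FALSE, n, nrow(catalog), dimnames = list(ids, catalog$gesture_type))
  for (m in GESTURE_MODALITIES) {
    cols <- which(catalog$modality == m)
    size <- length(cols)
    n_core <- round(config$overlap_core * size)
    if (config$overlap_core > 0 && n_core == 0) {
      stop(sprintf("catalog too small for requested core in modality '%s'", m),
           call. = FALSE)
    }
    if (n_core > 0) present[, cols[seq_len(n_core)]] <- TRUE
    pool <- cols[setdiff(seq_len(size), seq_len(n_core))]
    if (length(pool) == 0) next
    if (config$individual_type_mode == "shared_pool") {
      draws <- matrix(runif(n * length(pool)) < config$extra_type_prob,
                      nrow = n)
      present[, pool] <- draws
    } else {
      share <- split(pool, rep_len(seq_len(n), length(pool)))
      for (i in seq_len(n)) {
        mine <- share[[as.character(i)]]
        if (!is.null(mine)) present[i, mine] <- TRUE
      }
    }
  }
  list(individuals = individuals, kin_pairs = kin_pairs,
       repertoires = repertoire_set(present, catalog), catalog = catalog)
}

# Stable per-dyad logit deviations for party co-membership (symmetric).
.dyad_party_effects <- function(ids, sd) {
  n <- length(ids)
  u <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    u[i, j] <- u[j, i] <- rnorm(1, 0, sd)
  }
  u
}

# Standardized off-diagonal kappa (zero matrix when kappa is constant, e.g.
# all repertoires identical).
.standardized_kappa <- function(reps) {
  K <- suppressMessages(kappa_matrix(reps, "all"))
  kk <- unclass(K)
  off <- kk[row(kk) != col(kk)]
  mu <- mean(off, na.rm = TRUE)
  s <- stats::sd(off, na.rm = TRUE)
  z <- kk
  if (is.na(s) || s == 0) {
    z[] <- 0
  } else {
    z[] <- (kk - mu) / s
  }
  z[is.na(z)] <- 0
  z
}

.sample1 <- function(x, ...) x[sample.int(length(x), 1, ...)]

#' Generate synthetic focal follows
#'
#' Simulates fission-fusion party membership, scans and gesture events for a
#' generated population. Party composition is drawn per follow with
#' dyad-specific inclusion probabilities; within a follow each scan draws
#' within-10-m membership, a nearest neighbour, its distance, mutual
#' attention and activity states. The per-scan probability that a given
#' partner is the focal's nearest neighbour within 2 m increases on the
#' logit scale with `bonding_effect` times the dyad's standardized
#' repertoire kappa — the planted association that the rate, network and
#' permutation-inference stages are expected to recover. Gesture events are
#' drawn from the signaller's repertoire towards party members, with
#' response types distributed according to whether the gesture is
#' homogeneous (present in the recipient's repertoire; emotional responses
#' with probability `emotional_response_prob_homog`) or heterogeneous
#' (goal-directed responses with probability `goal_response_prob_heterog`).
#'
#' A single stream seeds the whole run: per-follow sub-seeds are drawn
#' up-front from `config$seed`, so output is byte-identical across runs with
#' the same configuration.
#'
#' @param config a [synthetic_config()].
#' @param population output of [generate_population()].
#' @return list with `scans` and `gestures` data frames in the package's
#'   standard layouts.
#' @export
generate_follows <- function(config, population) {
  set.seed(config$seed + 1L)
  ids <- population$individuals$id
  n <- length(ids)
  reps <- population$repertoires
  zk <- .standardized_kappa(reps)
  u_party <- .dyad_party_effects(ids, config$dyad_overlap_sd)
  follow_seeds <- sample.int(.Machine$integer.max - 1L, config$n_follows)
  duration_s <- config$scans_per_follow * config$scan_interval_min * 60
  base_party <- qlogis(min(max(config$party_prob, 1e-6), 1 - 1e-6))
  scan_rows <- vector("list", config$n_follows)
  gesture_rows <- vector("list", config$n_follows)
  act_probs <- c(feed = 0.30, rest = 0.25, travel = 0.15, groom_give = 0.08,
                 groom_receive = 0.07, groom_mutual = 0.05, other = 0.10)
  matched_act <- c(feed = "feed", rest = "rest", travel = "travel",
                   groom_give = "groom_receive", groom_receive = "groom_give",
                   groom_mutual = "groom_mutual", other = "other")
  acts <- names(act_probs)
  for (f in seq_len(config$n_follows)) {
    set.seed(follow_seeds[f])
    focal <- ids[((f - 1L) %% n) + 1L]
    follow_id <- sprintf("F%04d", f)
    others <- setdiff(ids, focal)
    in_party <- others[runif(length(others)) <
                         plogis(base_party + u_party[focal, others])]
    party <- c(focal, in_party)
    ns <- config$scans_per_follow
    w10_list <- vector("list", ns)
    nn <- rep(NA_character_, ns)
    nn_dist <- rep(NA_real_, ns)
    attention <- rep(NA, ns)
    focal_act <- sample(acts, ns, replace = TRUE, prob = act_probs)
    nn_act <- rep(NA_character_, ns)
    for (s in seq_len(ns)) {
      w10 <- in_party[runif(length(in_party)) < config$within_10m_prob]
      w10_list[[s]] <- w10
      if (length(w10) > 0) {
        nn[s] <- .sample1(w10)
        p2 <- plogis(config$proximity_base + config$bonding_effect * zk[focal, nn[s]])
        nn_dist[s] <- round(if (runif(1) < p2) runif(1, 0.1, 2) else runif(1, 2.1, 10), 2)
        attention[s] <- runif(1) < if (nn_dist[s] <= 2) 0.6 else 0.25
        nn_act[s] <- if (nn_dist[s] <= 2 && runif(1) < 0.6) {
          matched_act[[focal_act[s]]]
        } else {
          .sample1(acts, prob = act_probs)
        }
      }
    }
    sc <- data.frame(
      follow_id = follow_id, focal_id = focal, scan_index = seq_len(ns),
      nn_id = nn, nn_distance_m = nn_dist, attention_present = attention,
      focal_activity = focal_act, nn_activity = nn_act,
      stringsAsFactors = FALSE)
    sc$within_10m_ids <- I(w10_list)
    sc$party_ids <- I(rep(list(party), ns))
    scan_rows[[f]] <- sc
    n_ev <- rpois(1, config$gesture_rate_per_follow)
    sig_types <- names(which(reps$present[focal, ]))
    if (n_ev > 0 && length(in_party) > 0 && length(sig_types) > 0) {
      times <- sort(round(runif(n_ev, 0, duration_s), 1))
      scan_idx <- pmin(ns, pmax(1L, ceiling(times / (config$scan_interval_min * 60))))
      recipient <- in_party[sample.int(length(in_party), n_ev, replace = TRUE)]
      g_type <- sig_types[sample.int(length(sig_types), n_ev, replace = TRUE)]
      modality <- reps$catalog$modality[match(g_type, reps$catalog$gesture_type)]
      homog <- reps$present[cbind(recipient, g_type)]
      resp_present <- runif(n_ev) < ifelse(homog, 0.75, 0.55)
      u <- runif(n_ev)
      resp_type <- ifelse(!resp_present, "none",
        ifelse(homog,
               ifelse(u < config$emotional_response_prob_homog, "emotional", "goal_directed"),
               ifelse(u < config$goal_response_prob_heterog, "goal_directed", "emotional")))
      ev <- data.frame(
        event_id = sprintf("%s_e%03d", follow_id, seq_len(n_ev)),
        sequence_id = NA_character_,
        time_s = times,
        signaller_id = focal, recipient_id = recipient,
        gesture_type = g_type, modality = modality,
        panthoot = runif(n_ev) < config$panthoot_prob,
        response_present = resp_present,
        response_type = resp_type,
        vocal_response = resp_present & runif(n_ev) < 0.25,
        context = focal_act[scan_idx],
        follow_id = follow_id,
        stringsAsFactors = FALSE)
      ev$audience_10m_ids <- I(w10_list[scan_idx])
      gesture_rows[[f]] <- ev
    }
  }
  scans <- do.call(rbind, scan_rows)
  rownames(scans) <- NULL
  gesture_rows <- gesture_rows[!vapply(gesture_rows, is.null, logical(1))]
  gestures <- if (length(gesture_rows)) {
    g <- do.call(rbind, gesture_rows)
    rownames(g) <- NULL
    g
  } else {
    data.frame(event_id = character(0), sequence_id = character(0),
               time_s = numeric(0), signaller_id = character(0),
               recipient_id = character(0), gesture_type = character(0),
               modality = character(0), panthoot = logical(0),
               response_present = logical(0), response_type = character(0),
               vocal_response = logical(0),
               audience_10m_ids = I(list()), context = character(0),
               follow_id = character(0), stringsAsFactors = FALSE)
  }
  list(scans = scans, gestures = gestures)
}

#' Generate a complete synthetic dataset
#'
#' Population plus follows in one call; deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `config`, `individuals`, `kin_pairs`, `repertoires`,
#'   `catalog`, `scans`, `gestures`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  pop <- generate_population(config)
  fol <- generate_follows(config, pop)
  c(list(config = config), pop, fol)
}
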