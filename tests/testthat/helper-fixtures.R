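# Small in-code fixtures shared across the test files.

make_individuals <- function() {
  data.frame(
    id = c("AA", "BC", "CD", "DE"),
    sex = c("male", "male", "female", "female"),
    birth_year = c(1991L, 1993L, 1987L, NA),
    reproductive_status = c("not_applicable", "not_applicable", "oestrous", "cycling"),
    pantgrunt_indegree = c(0.5, 1.2, 0, 0),
    pantgrunt_outdegree = c(0.3, 0.1, 0.6, 0.4),
    stringsAsFactors = FALSE
  )
}

make_scans <- function() {
  sc <- data.frame(
    follow_id = c("F1", "F1", "F2"),
    focal_id = c("AA", "AA", "BC"),
    scan_index = c(1L, 2L, 1L),
    nn_id = c("BC", "CD", NA),
    nn_distance_m = c(1.5, 4, NA),
    attention_present = c(TRUE, FALSE, NA),
    focal_activity = c("feed", "rest", "travel"),
    nn_activity = c("feed", "rest", NA),
    stringsAsFactors = FALSE
  )
  sc$within_10m_ids <- I(list(c("BC", "CD"), "CD", character(0)))
  sc$party_ids <- I(list(c("AA", "BC", "CD"), c("AA", "CD"), c("BC", "DE")))
  sc
}

make_gestures <- function() {
  g <- data.frame(
    event_id = sprintf("e%02d", 1:4),
    sequence_id = NA_character_,
    time_s = c(10, 15, 60, 65),
    signaller_id = c("AA", "AA", "AA", "BC"),
    recipient_id = c("BC", "BC", "CD", "AA"),
    gesture_type = c("arm_beckon", "stomp", "arm_beckon", "slap_object"),
    modality = c("visual", "auditory_short", "visual", "auditory_short"),
    panthoot = c(FALSE, FALSE, FALSE, FALSE),
    response_present = c(TRUE, FALSE, TRUE, NA),
    response_type = c("emotional", "none", "goal_directed", NA),
    vocal_response = c(FALSE, FALSE, FALSE, NA),
    stringsAsFactors = FALSE
  )
  g$audience_10m_ids <- I(list(c("BC", "CD"), c("BC"), c("CD", "BC"), character(0)))
  g$follow_id <- c("F1", "F1", "F1", "F2")
  g
}

# Repertoire set over a small catalog from explicit type lists.
make_repertoire_set <- function(types_by_id, catalog) {
  ids <- names(types_by_id)
  present <- matrix(FALSE, length(ids), nrow(catalog),
                    dimnames = list(ids, catalog$gesture_type))
  for (id in ids) present[id, types_by_id[[id]]] <- TRUE
  repertoire_set(present, catalog)
}

simple_catalog <- function(n = 12, modality = "visual") {
  data.frame(gesture_type = sprintf("g%02d", seq_len(n)),
             modality = modality, stringsAsFactors = FALSE)
}

# Random dyadic matrix over n nodes.
random_dyad_matrix <- function(n, directed = TRUE, ids = sprintf("N%02d", seq_len(n))) {
  m <- matrix(rnorm(n * n), n, n, dimnames = list(ids, ids))
  if (!directed) m <- (m + t(m)) / 2
  as_dyad_matrix(m, directed = directed)
}
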