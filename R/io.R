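# CSV readers and writers for scan, gesture, individual and matrix files.
#
# Conventions shared by all tabular files:
#   * UTF-8 CSV with a header row;
#   * identifier sets (party membership, audience) are semicolon-separated
#     within one cell;
#   * the numeric code 999 denotes a missing value and is never data;
#   * scan indices are 1-based, times are follow-relative seconds.

.split_ids <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

.join_ids <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

# Parse a character column as numeric, mapping the 999 sentinel (and empty
# cells) to NA. Errors name the offending column and row.
.parse_num <- function(x, col) {
  blank <- is.na(x) | x == ""
  v <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(v)
  if (any(bad)) {
    stop(sprintf("malformed value '%s' in column '%s' (row %d)",
                 x[which(bad)[1]], col, which(bad)[1]), call. = FALSE)
  }
  v[!is.na(v) & v == MISSING_CODE] <- NA_real_
  v
}

# Parse a 0/1 flag column (999 or blank -> NA).
.parse_flag <- function(x, col) {
  v <- .parse_num(x, col)
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) {
    stop(sprintf("flag column '%s' must be 0/1/999 (row %d)",
                 col, which(bad)[1]), call. = FALSE)
  }
  v == 1
}

# Identifier column: blank or "999" means missing.
.parse_id <- function(x) {
  x[is.na(x) | x == "" | x == as.character(MISSING_CODE)] <- NA_character_
  x
}

.parse_cat <- function(x, col, levels) {
  v <- .parse_id(x)
  bad <- !is.na(v) & !(v %in% levels)
  if (any(bad)) {
    stop(sprintf("unknown level '%s' in column '%s' (row %d); expected one of %s",
                 v[which(bad)[1]], col, which(bad)[1],
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  v
}

.require_cols <- function(raw, cols, what) {
  miss <- setdiff(cols, names(raw))
  if (length(miss)) {
    stop(sprintf("%s file is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

.check_known_ids <- function(ids, known, what) {
  ids <- unique(ids[!is.na(ids)])
  bad <- setdiff(ids, known)
  if (length(bad)) {
    stop(sprintf("unknown individual id(s) in %s: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Read focal-follow scan records
#'
#' Reads instantaneous scan samples taken during focal-animal follows. Each
#' row is one scan of one follow: who was within 10 m of the focal animal,
#' who was in the same party (a subgroup within roughly 35 m spread), the
#' nearest adult neighbour with its distance, whether mutual visual attention
#' was present, and the activity of focal and neighbour.
#'
#' The sentinel 999 in any numeric column, and blank or 999 identifier cells,
#' are parsed as missing. Row-level invariants are validated: the scan index
#' must lie in `1:max_scan_index`, the focal must belong to its own party,
#' every individual within 10 m must also be in the party, the nearest
#' neighbour must differ from the focal, and distances must be nonnegative.
#'
#' @param path path to a scans CSV with columns `follow_id`, `focal_id`,
#'   `scan_index`, `within_10m_ids`, `party_ids`, `nn_id`, `nn_distance_m`,
#'   `attention_present`, `focal_activity`, `nn_activity`. Identifier sets
#'   are semicolon-separated.
#' @param individuals optional individual attribute table (see
#'   [read_individuals()]); when given, every id in the file must occur in it.
#' @param max_scan_index largest legal scan index (default 9, i.e. nine scans
#'   at 2-min intervals over an 18-min follow).
#' @return a `data.frame` with one row per scan; `within_10m_ids` and
#'   `party_ids` are list columns of character vectors.
#' @export
read_scans <- function(path, individuals = NULL, max_scan_index = 9) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .require_cols(raw, c("follow_id", "focal_id", "scan_index", "within_10m_ids",
                       "party_ids", "nn_id", "nn_distance_m",
                       "attention_present", "focal_activity", "nn_activity"),
                "scans")
  scans <- data.frame(
    follow_id = .parse_id(raw$follow_id),
    focal_id = .parse_id(raw$focal_id),
    scan_index = as.integer(.parse_num(raw$scan_index, "scan_index")),
    stringsAsFactors = FALSE
  )
  scans$within_10m_ids <- I(.split_ids(raw$within_10m_ids))
  scans$party_ids <- I(.split_ids(raw$party_ids))
  scans$nn_id <- .parse_id(raw$nn_id)
  scans$nn_distance_m <- .parse_num(raw$nn_distance_m, "nn_distance_m")
  scans$attention_present <- .parse_flag(raw$attention_present, "attention_present")
  scans$focal_activity <- .parse_cat(raw$focal_activity, "focal_activity", FOCAL_ACTIVITIES)
  scans$nn_activity <- .parse_cat(raw$nn_activity, "nn_activity", FOCAL_ACTIVITIES)
  validate_scans(scans, individuals = individuals, max_scan_index = max_scan_index)
  scans
}

#' Validate scan records
#'
#' Checks the row-level invariants described in [read_scans()]. Called by the
#' reader, and usable directly on programmatically built scan tables.
#'
#' @inheritParams read_scans
#' @param scans a scan `data.frame` in the layout produced by [read_scans()].
#' @return `scans`, invisibly, if valid; otherwise an error naming the first
#'   offending row and field.
#' @export
validate_scans <- function(scans, individuals = NULL, max_scan_index = 9) {
  for (i in seq_len(nrow(scans))) {
    row <- scans[i, ]
    if (is.na(row$follow_id) || is.na(row$focal_id)) {
      stop(sprintf("scan row %d: follow_id and focal_id are required", i), call. = FALSE)
    }
    if (is.na(row$scan_index) || row$scan_index < 1 || row$scan_index > max_scan_index) {
      stop(sprintf("scan row %d: scan_index must be in 1..%d (field scan_index)",
                   i, max_scan_index), call. = FALSE)
    }
    party <- row$party_ids[[1]]
    if (!(row$focal_id %in% party)) {
      stop(sprintf("scan row %d: focal_id '%s' not in party_ids (field party_ids)",
                   i, row$focal_id), call. = FALSE)
    }
    w10 <- row$within_10m_ids[[1]]
    if (length(setdiff(w10, party))) {
      stop(sprintf("scan row %d: within_10m_ids not a subset of party_ids (field within_10m_ids)", i),
           call. = FALSE)
    }
    if (!is.na(row$nn_id) && row$nn_id == row$focal_id) {
      stop(sprintf("scan row %d: nn_id equals focal_id (field nn_id)", i), call. = FALSE)
    }
    if (!is.na(row$nn_distance_m) && row$nn_distance_m < 0) {
      stop(sprintf("scan row %d: nn_distance_m is negative (field nn_distance_m)", i),
           call. = FALSE)
    }
  }
  if (!is.null(individuals)) {
    .check_known_ids(c(scans$focal_id, scans$nn_id,
                       unlist(scans$within_10m_ids), unlist(scans$party_ids)),
                     individuals$id, "scans")
  }
  invisible(scans)
}

#' Write scan records
#'
#' Inverse of [read_scans()]: missing numeric values are written as 999,
#' missing identifiers as empty cells, flags as 0/1.
#'
#' @param scans a scan `data.frame` as returned by [read_scans()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(
    follow_id = scans$follow_id,
    focal_id = scans$focal_id,
    scan_index = scans$scan_index,
    within_10m_ids = .join_ids(scans$within_10m_ids),
    party_ids = .join_ids(scans$party_ids),
    nn_id = ifelse(is.na(scans$nn_id), "", scans$nn_id),
    nn_distance_m = ifelse(is.na(scans$nn_distance_m), MISSING_CODE, scans$nn_distance_m),
    attention_present = ifelse(is.na(scans$attention_present), MISSING_CODE,
                               as.integer(scans$attention_present)),
    focal_activity = ifelse(is.na(scans$focal_activity), "", scans$focal_activity),
    nn_activity = ifelse(is.na(scans$nn_activity), "", scans$nn_activity),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read gesture event records
#'
#' Reads one intentional gesture per row: signaller, recipient, gesture type,
#' sensory modality (visual, tactile, short- or long-range auditory), whether
#' the gesture was accompanied by a panthoot call, the recipient's response
#' (presence, kind, vocal component), and the identities within 10 m at the
#' time of the gesture. An optional `context` column carries the behavioural
#' context used when grouping gestures into sequences; an optional
#' `follow_id` column links events to the focal follow they occurred in.
#'
#' Validated invariants: signaller differs from recipient; modality is one of
#' the four recognized values; `response_type` is `"none"` exactly when
#' `response_present` is false (when both are observed).
#'
#' @param path path to a gestures CSV with columns `event_id`, `sequence_id`,
#'   `time_s`, `signaller_id`, `recipient_id`, `gesture_type`, `modality`,
#'   `panthoot`, `response_present`, `response_type`, `vocal_response`,
#'   `audience_10m_ids` (and optionally `context`, `follow_id`).
#' @param individuals optional individual table used to reject unknown ids.
#' @return a `data.frame` with one row per gesture event; `audience_10m_ids`
#'   is a list column.
#' @export
read_gestures <- function(path, individuals = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .require_cols(raw, c("event_id", "sequence_id", "time_s", "signaller_id",
                       "recipient_id", "gesture_type", "modality", "panthoot",
                       "response_present", "response_type", "vocal_response",
                       "audience_10m_ids"),
                "gestures")
  ev <- data.frame(
    event_id = .parse_id(raw$event_id),
    sequence_id = .parse_id(raw$sequence_id),
    time_s = .parse_num(raw$time_s, "time_s"),
    signaller_id = .parse_id(raw$signaller_id),
    recipient_id = .parse_id(raw$recipient_id),
    gesture_type = .parse_id(raw$gesture_type),
    modality = .parse_cat(raw$modality, "modality", GESTURE_MODALITIES),
    panthoot = .parse_flag(raw$panthoot, "panthoot"),
    response_present = .parse_flag(raw$response_present, "response_present"),
    response_type = .parse_cat(raw$response_type, "response_type", RESPONSE_TYPES),
    vocal_response = .parse_flag(raw$vocal_response, "vocal_response"),
    stringsAsFactors = FALSE
  )
  ev$audience_10m_ids <- I(.split_ids(raw$audience_10m_ids))
  if ("context" %in% names(raw)) ev$context <- .parse_id(raw$context)
  if ("follow_id" %in% names(raw)) ev$follow_id <- .parse_id(raw$follow_id)
  validate_gestures(ev, individuals = individuals)
  ev
}

#' Validate gesture events
#'
#' @param events a gesture `data.frame` in the layout produced by
#'   [read_gestures()].
#' @inheritParams read_gestures
#' @return `events`, invisibly, if valid.
#' @export
validate_gestures <- function(events, individuals = NULL) {
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    if (is.na(row$event_id) || is.na(row$signaller_id) || is.na(row$gesture_type)) {
      stop(sprintf("gesture row %d: event_id, signaller_id and gesture_type are required", i),
           call. = FALSE)
    }
    if (!is.na(row$recipient_id) && row$recipient_id == row$signaller_id) {
      stop(sprintf("gesture row %d: signaller equals recipient (field recipient_id)", i),
           call. = FALSE)
    }
    if (is.na(row$modality)) {
      stop(sprintf("gesture row %d: modality is required (field modality)", i), call. = FALSE)
    }
    if (!is.na(row$response_present) && !is.na(row$response_type)) {
      if (xor(row$response_type == "none", !row$response_present)) {
        stop(sprintf("gesture row %d: response_type must be 'none' exactly when response_present is 0 (field response_type)", i),
             call. = FALSE)
      }
    }
  }
  if (!is.null(individuals)) {
    .check_known_ids(c(events$signaller_id, events$recipient_id,
                       unlist(events$audience_10m_ids)),
                     individuals$id, "gestures")
  }
  invisible(events)
}

#' Write gesture events
#'
#' @param events a gesture `data.frame` as returned by [read_gestures()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gestures <- function(events, path) {
  chr <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(
    event_id = chr(events$event_id),
    sequence_id = chr(events$sequence_id),
    time_s = ifelse(is.na(events$time_s), MISSING_CODE, events$time_s),
    signaller_id = chr(events$signaller_id),
    recipient_id = chr(events$recipient_id),
    gesture_type = chr(events$gesture_type),
    modality = chr(events$modality),
    panthoot = ifelse(is.na(events$panthoot), MISSING_CODE, as.integer(events$panthoot)),
    response_present = ifelse(is.na(events$response_present), MISSING_CODE,
                              as.integer(events$response_present)),
    response_type = chr(events$response_type),
    vocal_response = ifelse(is.na(events$vocal_response), MISSING_CODE,
                            as.integer(events$vocal_response)),
    audience_10m_ids = .join_ids(events$audience_10m_ids),
    stringsAsFactors = FALSE
  )
  if ("context" %in% names(events)) out$context <- chr(events$context)
  if ("follow_id" %in% names(events)) out$follow_id <- chr(events$follow_id)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the individual attribute table
#'
#' One row per study subject: sex, birth year (the point estimate; an
#' optional `birth_year_uncertainty` column records +/- years where the exact
#' year is unknown), female reproductive status, and pantgrunt given
#' indegree/outdegree. Pantgrunting is a submissive vocalization, so pantgrunt
#' degrees index dominance. The packaged fixture
#' `system.file("extdata", "sonso_individuals.csv", package = "gesturenet")`
#' carries the demographic table of the 12-subject study group.
#'
#' @param path path to an individuals CSV with columns `id`, `sex`,
#'   `birth_year`, `reproductive_status`, `pantgrunt_indegree`,
#'   `pantgrunt_outdegree`.
#' @return a `data.frame`, one row per individual.
#' @export
read_individuals <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .require_cols(raw, c("id", "sex", "birth_year", "reproductive_status",
                       "pantgrunt_indegree", "pantgrunt_outdegree"),
                "individuals")
  ind <- data.frame(
    id = .parse_id(raw$id),
    sex = .parse_cat(raw$sex, "sex", c("male", "female")),
    birth_year = as.integer(.parse_num(raw$birth_year, "birth_year")),
    reproductive_status = .parse_cat(raw$reproductive_status, "reproductive_status",
                                     c("cycling", "pregnant", "nursing", "oestrous",
                                       "not_applicable")),
    pantgrunt_indegree = .parse_num(raw$pantgrunt_indegree, "pantgrunt_indegree"),
    pantgrunt_outdegree = .parse_num(raw$pantgrunt_outdegree, "pantgrunt_outdegree"),
    stringsAsFactors = FALSE
  )
  if ("birth_year_uncertainty" %in% names(raw)) {
    ind$birth_year_uncertainty <- .parse_num(raw$birth_year_uncertainty,
                                             "birth_year_uncertainty")
  }
  if (anyDuplicated(ind$id)) {
    stop("individual ids must be unique", call. = FALSE)
  }
  if (any(!is.na(ind$pantgrunt_indegree) & ind$pantgrunt_indegree < 0) ||
      any(!is.na(ind$pantgrunt_outdegree) & ind$pantgrunt_outdegree < 0)) {
    stop("pantgrunt degrees must be nonnegative", call. = FALSE)
  }
  ind
}

#' Write the individual attribute table
#'
#' @param individuals a `data.frame` as returned by [read_individuals()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(individuals, path) {
  out <- individuals
  for (col in c("birth_year", "pantgrunt_indegree", "pantgrunt_outdegree",
                "birth_year_uncertainty")) {
    if (col %in% names(out)) {
      out[[col]] <- ifelse(is.na(out[[col]]), MISSING_CODE, out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read maternal kin pairs
#'
#' @param path CSV with columns `id_a`, `id_b`, one unordered maternally
#'   related pair per row.
#' @return a `data.frame` with columns `id_a`, `id_b`.
#' @export
read_kin_pairs <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .require_cols(raw, c("id_a", "id_b"), "kin pairs")
  data.frame(id_a = .parse_id(raw$id_a), id_b = .parse_id(raw$id_b),
             stringsAsFactors = FALSE)
}

#' Write maternal kin pairs
#'
#' @param kin_pairs a `data.frame` with columns `id_a`, `id_b`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kin_pairs <- function(kin_pairs, path) {
  utils::write.csv(kin_pairs[, c("id_a", "id_b")], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a labelled square dyadic matrix
#'
#' First row and first column hold the node ids; the diagonal is written
#' blank (it is structurally undefined for dyadic data), as are missing ties.
#'
#' @param m a [dyad_matrix()] or plain square matrix with dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  mm <- unclass(m)
  diag(mm) <- NA
  out <- cbind(id = rownames(mm), as.data.frame(mm, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a labelled square dyadic matrix
#'
#' @param path path to a matrix CSV written by [write_matrix_csv()].
#' @param directed whether the stored network is directed; undirected
#'   matrices are checked for symmetry.
#' @return a [dyad_matrix()].
#' @export
read_matrix_csv <- function(path, directed = TRUE) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  ids <- as.character(raw[[1]])
  mm <- as.matrix(raw[, -1, drop = FALSE])
  if (!identical(colnames(mm), ids)) {
    stop("matrix file is not square or row/column labels disagree", call. = FALSE)
  }
  storage.mode(mm) <- "double"
  rownames(mm) <- ids
  as_dyad_matrix(mm, directed = directed)
}
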