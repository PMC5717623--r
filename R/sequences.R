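# Gesture sequence assembly and the panthoot recipient-assignment rule.

#' Group gesture events into sequences
#'
#' A gesture sequence is one or more gestures made consecutively by the same
#' signaller towards the same recipient, within the same behavioural context,
#' with at most `max_gap_s` seconds between consecutive gestures. Events are
#' grouped per signaller in time order; a change of recipient or context, or
#' a gap exceeding the threshold, starts a new sequence.
#'
#' If the events carry no `context` column, context is ignored in the
#' grouping. Sequence ids are deterministic (`<signaller>_seq<k>` in time
#' order within signaller), so grouping is idempotent and invariant to any
#' stable re-sorting of the input rows.
#'
#' @param events gesture event table ([read_gestures()]).
#' @param max_gap_s maximum within-sequence gap between consecutive gestures,
#'   in seconds (default 30).
#' @return `events` with `sequence_id` filled in, rows in the original order.
#' @export
group_sequences <- function(events, max_gap_s = 30) {
  if (nrow(events) == 0) {
    events$sequence_id <- character(0)
    return(events)
  }
  ctx <- if ("context" %in% names(events)) events$context else rep(NA_character_, nrow(events))
  flw <- if ("follow_id" %in% names(events)) events$follow_id else rep(NA_character_, nrow(events))
  same <- function(x, y) (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && x == y)
  ord <- order(events$signaller_id, flw, events$time_s, events$event_id)
  seq_ids <- character(nrow(events))
  counter <- 0L
  cur_sig <- NA_character_
  for (k in seq_along(ord)) {
    i <- ord[k]
    new_seq <- TRUE
    if (k > 1) {
      p <- ord[k - 1]
      new_seq <- !(events$signaller_id[i] == events$signaller_id[p] &&
                   same(events$recipient_id[i], events$recipient_id[p]) &&
                   same(ctx[i], ctx[p]) &&
                   same(flw[i], flw[p]) &&
                   !is.na(events$time_s[i]) && !is.na(events$time_s[p]) &&
                   events$time_s[i] - events$time_s[p] <= max_gap_s)
    }
    if (!identical(cur_sig, events$signaller_id[i])) {
      cur_sig <- events$signaller_id[i]
      counter <- 0L
    }
    if (new_seq) counter <- counter + 1L
    seq_ids[i] <- sprintf("%s_seq%03d", events$signaller_id[i], counter)
  }
  events$sequence_id <- seq_ids
  events
}

#' Recipient of a panthoot-accompanied gesture sequence
#'
#' Gestures accompanied by a panthoot (a long-distance broadcast
#' vocalization) have no single addressee observable in the field, so the
#' recipient is assigned by rule: a sequence consisting solely of visual
#' gestures plus panthoot is counted as directed at the most dominant
#' individual in the signaller's party, whereas a sequence containing any
#' auditory gesture plus panthoot is taken to be directed at the focal
#' individual's nearest neighbour. Sequences without a panthoot, and
#' panthoot sequences that are neither all-visual nor contain an auditory
#' gesture (e.g. tactile mixes), keep their recorded recipient.
#'
#' @param sequence the events of one gesture sequence (a gesture
#'   `data.frame`), all sharing one `sequence_id`.
#' @param scan the [read_scans()] row giving party membership and nearest
#'   neighbour at the time of the sequence.
#' @param dominance character vector of ids, most dominant first (see
#'   [dominance_order()]).
#' @return the assigned recipient id, or `NA` (with a message) when the rule
#'   needs a nearest neighbour that was not recorded; such sequences should
#'   be flagged unusable by the caller.
#' @export
panthoot_recipient <- function(sequence, scan, dominance) {
  recorded <- sequence$recipient_id[1]
  if (!any(sequence$panthoot, na.rm = TRUE)) return(recorded)
  mods <- unique(sequence$modality)
  signaller <- sequence$signaller_id[1]
  if (any(mods %in% c("auditory_short", "auditory_long"))) {
    nn <- scan$nn_id
    if (is.na(nn)) {
      message(sprintf("sequence %s: auditory panthoot but no nearest neighbour recorded; unusable",
                      sequence$sequence_id[1]))
      return(NA_character_)
    }
    return(nn)
  }
  if (all(mods == "visual")) {
    party <- setdiff(scan$party_ids[[1]], signaller)
    ranked <- dominance[dominance %in% party]
    if (length(ranked) == 0) {
      message(sprintf("sequence %s: no ranked party member available; unusable",
                      sequence$sequence_id[1]))
      return(NA_character_)
    }
    return(ranked[1])
  }
  recorded
}

#' Apply the panthoot recipient rule across a gesture table
#'
#' Splits events by `sequence_id`, locates the scan of the same follow
#' closest to each sequence's first gesture, and rewrites the recipient of
#' every event in sequences where [panthoot_recipient()] assigns one.
#' Sequences the rule cannot resolve get `NA` recipients.
#'
#' @param events gesture events with `sequence_id` and `follow_id` filled.
#' @param scans scan table ([read_scans()]).
#' @param dominance ids, most dominant first.
#' @param scan_interval_min minutes between consecutive scans (default 2).
#' @return `events` with recipients reassigned where the rule applies.
#' @export
assign_panthoot_recipients <- function(events, scans, dominance,
                                       scan_interval_min = 2) {
  if (nrow(events) == 0) return(events)
  if (!"follow_id" %in% names(events)) {
    stop("events need a follow_id column to be matched to scans", call. = FALSE)
  }
  for (sid in unique(events$sequence_id)) {
    rows <- which(events$sequence_id == sid)
    seq_ev <- events[rows, ]
    if (!any(seq_ev$panthoot, na.rm = TRUE)) next
    fol <- scans[scans$follow_id == seq_ev$follow_id[1], ]
    if (nrow(fol) == 0) {
      stop(sprintf("sequence %s: no scans for follow '%s'", sid, seq_ev$follow_id[1]),
           call. = FALSE)
    }
    want <- ceiling(min(seq_ev$time_s, na.rm = TRUE) / (scan_interval_min * 60))
    scan <- fol[which.min(abs(fol$scan_index - want)), ]
    events$recipient_id[rows] <- panthoot_recipient(seq_ev, scan, dominance)
  }
  events
}
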