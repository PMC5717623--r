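# Repertoire construction, the intentionality filter, Cohen's kappa and
# homogeneous/heterogeneous repertoire sizes at dyad and sequence level.

#' Intentionality filter for gesture types
#'
#' A gesture type is retained as intentional when the fraction of its
#' occurrences satisfying the intentionality criteria (audience present,
#' response waiting, sensitivity to the recipient's attention, persistence),
#' pooled across subjects, exceeds the threshold. The published rule reads
#' "above the threshold of 60%", implemented here as strictly greater than
#' `threshold`; set `strict = FALSE` for a greater-or-equal reading. Types
#' with zero scored occurrences are excluded and logged.
#'
#' @param criteria `data.frame` with one row per gesture type: column
#'   `gesture_type` plus either `fraction` (fraction of occurrences meeting
#'   the criteria) or both `n_intentional` and `n_total`.
#' @param threshold retention threshold on the intentional fraction.
#' @param strict retain strictly above (`TRUE`, default) or at-or-above the
#'   threshold.
#' @return character vector of retained gesture types.
#' @export
intentionality_filter <- function(criteria, threshold = 0.60, strict = TRUE) {
  if (!"fraction" %in% names(criteria)) {
    if (!all(c("n_intentional", "n_total") %in% names(criteria))) {
      stop("criteria need either a 'fraction' column or 'n_intentional' + 'n_total'",
           call. = FALSE)
    }
    criteria$fraction <- ifelse(criteria$n_total > 0,
                                criteria$n_intentional / criteria$n_total, NA_real_)
    zero <- criteria$n_total == 0
    if (any(zero)) {
      message(sprintf("excluding %d gesture type(s) with zero scored occurrences: %s",
                      sum(zero), paste(criteria$gesture_type[zero], collapse = ", ")))
    }
  }
  keep <- if (strict) criteria$fraction > threshold else criteria$fraction >= threshold
  keep[is.na(keep)] <- FALSE
  criteria$gesture_type[keep]
}

#' Build per-individual gesture repertoires
#'
#' A gesture type belongs to an individual's repertoire when that individual
#' produced it as signaller at least once towards an adult recipient. Events
#' towards recipients outside `adults` (e.g. juveniles) do not contribute.
#'
#' @param events gesture event table ([read_gestures()]).
#' @param adults ids of the adult individuals; repertoires are built for
#'   these individuals and only gestures towards them count.
#' @param catalog the gesture-type catalog: `data.frame` with columns
#'   `gesture_type`, `modality`. Defaults to the distinct types observed in
#'   `events`.
#' @return a `repertoire_set`: list with `present` (logical matrix,
#'   individuals by catalog types) and `catalog`.
#' @export
build_repertoires <- function(events, adults, catalog = NULL) {
  if (is.null(catalog)) {
    keep <- !duplicated(events$gesture_type)
    catalog <- data.frame(gesture_type = events$gesture_type[keep],
                          modality = events$modality[keep],
                          stringsAsFactors = FALSE)
    catalog <- catalog[order(catalog$modality, catalog$gesture_type), ]
  }
  present <- matrix(FALSE, nrow = length(adults), ncol = nrow(catalog),
                    dimnames = list(adults, catalog$gesture_type))
  use <- events$signaller_id %in% adults &
         !is.na(events$recipient_id) & events$recipient_id %in% adults &
         events$gesture_type %in% catalog$gesture_type
  for (i in which(use)) {
    present[events$signaller_id[i], events$gesture_type[i]] <- TRUE
  }
  repertoire_set(present, catalog)
}

#' Construct a repertoire set
#'
#' @param present logical matrix, individuals (rows) by gesture types
#'   (columns), both dimnamed.
#' @param catalog `data.frame` with columns `gesture_type`, `modality`
#'   matching the columns of `present`.
#' @return an object of class `repertoire_set`.
#' @export
repertoire_set <- function(present, catalog) {
  stopifnot(is.matrix(present), is.logical(present),
            identical(colnames(present), catalog$gesture_type))
  if (!all(catalog$modality %in% GESTURE_MODALITIES)) {
    stop("catalog modalities must be one of: ",
         paste(GESTURE_MODALITIES, collapse = ", "), call. = FALSE)
  }
  structure(list(present = present, catalog = catalog), class = "repertoire_set")
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat(sprintf("<repertoire_set> %d individuals x %d gesture types (%s)\n",
              nrow(x$present), ncol(x$present),
              paste(sprintf("%s: %d", names(table(x$catalog$modality)),
                            table(x$catalog$modality)), collapse = ", ")))
  invisible(x)
}

# Columns of the catalog belonging to one modality ("all" = full catalog).
.modality_cols <- function(reps, modality) {
  if (identical(modality, "all")) return(seq_len(nrow(reps$catalog)))
  if (!modality %in% GESTURE_MODALITIES) {
    stop(sprintf("unknown modality '%s'", modality), call. = FALSE)
  }
  which(reps$catalog$modality == modality)
}

#' Extract an individual's presence/absence vector
#'
#' @param reps a `repertoire_set`.
#' @param id individual id.
#' @param modality `"all"` (full catalog) or one of the four modalities; a
#'   per-modality vector ranges over that modality's catalog only, so
#'   per-modality agreement is independent of the other modalities' catalog
#'   sizes.
#' @return named logical vector over the selected catalog.
#' @export
repertoire_vector <- function(reps, id, modality = "all") {
  if (!id %in% rownames(reps$present)) {
    stop(sprintf("no repertoire for individual '%s'", id), call. = FALSE)
  }
  reps$present[id, .modality_cols(reps, modality)]
}

#' Cohen's kappa for two presence/absence vectors
#'
#' Chance-corrected agreement between two binary vectors over a common
#' catalog, computed from the 2x2 presence/absence contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and the
#' product-of-marginals expected agreement `p_e`. Identical non-constant
#' vectors give 1 (exactly the same repertoire); complementary vectors with
#' half the catalog present each give -1 (completely different repertoire).
#' When the expected agreement is 1 (e.g. both vectors constant) kappa is
#' undefined and `NA` is returned.
#'
#' @param a,b logical (or 0/1) vectors of equal length over the same catalog.
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    stop("presence vectors must have the same length", call. = FALSE)
  }
  if (length(a) == 0) stop("presence vectors must be non-empty", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  n <- length(a)
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) * (n11 + n01) + (n00 + n01) * (n00 + n10)) / n^2
  if (1 - p_e < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Dyadic repertoire summary
#'
#' For one dyad and one catalog universe, computes the homogeneous repertoire
#' size (number of gesture types present in both repertoires), the
#' heterogeneous repertoire size (types unique to either member,
#' `|A \ B| + |B \ A|`, symmetric in the dyad by construction), and Cohen's
#' kappa.
#'
#' @param reps a `repertoire_set`.
#' @param id_a,id_b the two individuals.
#' @param modality `"all"` or one of the four modalities.
#' @return one-row `data.frame` with columns `id_a`, `id_b`, `modality`,
#'   `homog_size`, `heterog_size`, `kappa`.
#' @export
dyad_repertoire_summary <- function(reps, id_a, id_b, modality = "all") {
  a <- repertoire_vector(reps, id_a, modality)
  b <- repertoire_vector(reps, id_b, modality)
  data.frame(id_a = id_a, id_b = id_b, modality = modality,
             homog_size = sum(a & b),
             heterog_size = sum(a & !b) + sum(!a & b),
             kappa = cohens_kappa(a, b),
             stringsAsFactors = FALSE)
}

#' Dyadic repertoire summaries for all ordered dyads
#'
#' @param reps a `repertoire_set`.
#' @param modalities catalog universes to compute, default the full catalog
#'   plus each modality separately.
#' @return `data.frame` with one row per ordered dyad and modality.
#' @export
dyad_summary_table <- function(reps, modalities = c("all", GESTURE_MODALITIES)) {
  ids <- rownames(reps$present)
  rows <- list()
  for (m in modalities) {
    for (i in ids) for (j in ids) {
      if (i == j) next
      rows[[length(rows) + 1L]] <- dyad_repertoire_summary(reps, i, j, m)
    }
  }
  do.call(rbind, rows)
}

#' Dyadic Cohen's kappa network
#'
#' Undirected dyadic matrix of repertoire agreement: the kappa between each
#' pair of repertoires over the selected catalog. Dyads with undefined kappa
#' (expected agreement 1, e.g. two empty modality repertoires) are missing
#' ties, logged and excluded downstream.
#'
#' @param reps a `repertoire_set`.
#' @param modality `"all"` or one of the four modalities.
#' @return an undirected [dyad_matrix()].
#' @export
kappa_matrix <- function(reps, modality = "all") {
  ids <- rownames(reps$present)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  n_undef <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      k <- cohens_kappa(repertoire_vector(reps, ids[i], modality),
                        repertoire_vector(reps, ids[j], modality))
      if (is.na(k)) n_undef <- n_undef + 1L
      m[i, j] <- k
      m[j, i] <- k
    }
  }
  if (n_undef > 0) {
    message(sprintf("kappa undefined for %d dyad(s) in modality '%s'; left missing",
                    n_undef, modality))
  }
  as_dyad_matrix(m, directed = FALSE)
}

#' Dyadic repertoire-size network
#'
#' Undirected dyadic matrix of the homogeneous (shared types) or
#' heterogeneous (types unique to either member) repertoire size.
#'
#' @param reps a `repertoire_set`.
#' @param type `"homogeneous"` or `"heterogeneous"`.
#' @param modality `"all"` or one of the four modalities.
#' @return an undirected [dyad_matrix()].
#' @export
repertoire_size_matrix <- function(reps, type = c("homogeneous", "heterogeneous"),
                                   modality = "all") {
  type <- match.arg(type)
  ids <- rownames(reps$present)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      s <- dyad_repertoire_summary(reps, ids[i], ids[j], modality)
      v <- if (type == "homogeneous") s$homog_size else s$heterog_size
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  as_dyad_matrix(m, directed = FALSE)
}

#' Classify the gesture types of one sequence as homogeneous or heterogeneous
#'
#' Each distinct gesture type used in the sequence is homogeneous when it is
#' present in both the signaller's and the recipient's repertoire, and
#' heterogeneous when the recipient lacks it. The homogeneous and
#' heterogeneous repertoire sizes of the sequence are the counts of distinct
#' types in each class, and sum to the number of distinct types used.
#'
#' Sequences whose recipient has no observed repertoire (not a focal subject,
#' or an entirely empty repertoire) are flagged and their labels left
#' missing, since homogeneity cannot be established against an unobserved
#' repertoire.
#'
#' @param sequence the events of one gesture sequence.
#' @param reps a `repertoire_set`.
#' @return a list with `labels` (named character vector over the distinct
#'   types: `"homogeneous"`/`"heterogeneous"` or `NA`),
#'   `homog_repertoire_size`, `heterog_repertoire_size`, and `flagged`.
#' @export
classify_sequence <- function(sequence, reps) {
  types <- unique(sequence$gesture_type)
  signaller <- sequence$signaller_id[1]
  recipient <- sequence$recipient_id[1]
  known <- function(id) !is.na(id) && id %in% rownames(reps$present) &&
    any(reps$present[id, ])
  if (!known(recipient)) {
    message(sprintf("sequence %s: recipient '%s' has no observed repertoire; flagged",
                    sequence$sequence_id[1], recipient))
    return(list(labels = setNames(rep(NA_character_, length(types)), types),
                homog_repertoire_size = NA_integer_,
                heterog_repertoire_size = NA_integer_,
                flagged = TRUE))
  }
  sig <- repertoire_vector(reps, signaller)
  rec <- repertoire_vector(reps, recipient)
  lab <- vapply(types, function(t) {
    if (t %in% names(sig) && sig[t] && rec[t]) "homogeneous" else "heterogeneous"
  }, character(1))
  list(labels = lab,
       homog_repertoire_size = sum(lab == "homogeneous"),
       heterog_repertoire_size = sum(lab == "heterogeneous"),
       flagged = FALSE)
}

#' Per-sequence homogeneity table for regression modelling
#'
#' One row per gesture sequence: signaller, recipient, overall and
#' per-modality homogeneous/heterogeneous repertoire sizes and presence
#' flags, plus the response fields of the sequence (a response is counted as
#' present when any gesture in the sequence drew one). Flagged sequences
#' (recipient repertoire unobserved) are retained with missing sizes.
#'
#' @param events gesture events with `sequence_id` assigned
#'   ([group_sequences()]).
#' @param reps a `repertoire_set`.
#' @return a `data.frame`, one row per sequence.
#' @export
sequence_homogeneity_table <- function(events, reps) {
  rows <- list()
  for (sid in unique(events$sequence_id)) {
    seq_ev <- events[events$sequence_id == sid, ]
    cls <- suppressMessages(classify_sequence(seq_ev, reps))
    row <- data.frame(
      sequence_id = sid,
      signaller_id = seq_ev$signaller_id[1],
      recipient_id = seq_ev$recipient_id[1],
      n_gestures = nrow(seq_ev),
      homog_size = cls$homog_repertoire_size,
      heterog_size = cls$heterog_repertoire_size,
      flagged = cls$flagged,
      response_present = as.integer(any(seq_ev$response_present, na.rm = TRUE)),
      emotional_response = as.integer(any(!is.na(seq_ev$response_type) &
                                          seq_ev$response_type == "emotional")),
      goal_directed_response = as.integer(any(!is.na(seq_ev$response_type) &
                                              seq_ev$response_type == "goal_directed")),
      vocal_response = as.integer(any(seq_ev$vocal_response, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
    for (m in GESTURE_MODALITIES) {
      mtypes <- names(cls$labels)[names(cls$labels) %in%
                                  reps$catalog$gesture_type[reps$catalog$modality == m]]
      lab <- cls$labels[mtypes]
      row[[paste0("homog_", m)]] <- if (cls$flagged) NA_integer_ else sum(lab == "homogeneous")
      row[[paste0("heterog_", m)]] <- if (cls$flagged) NA_integer_ else sum(lab == "heterogeneous")
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
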