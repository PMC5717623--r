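# Dyad attribute scoring and dominance ordering.

.is_kin <- function(a, b, kin_pairs) {
  if (is.null(kin_pairs) || nrow(kin_pairs) == 0) return(FALSE)
  any((kin_pairs$id_a == a & kin_pairs$id_b == b) |
      (kin_pairs$id_a == b & kin_pairs$id_b == a))
}

#' Score the demographic attributes of a dyad
#'
#' Computes the four control attributes used throughout the dyadic analyses:
#' same sex, same age class (birth years at most `age_class_window` years
#' apart, default 5), reproductively active (exactly one member is male and
#' the other an oestrous female; every other combination, including a male
#' with a cycling but non-oestrous female, is inactive), and maternal kinship.
#'
#' All four attributes are symmetric in the dyad. A missing birth year makes
#' the age-class flag missing (with a message) rather than an error.
#'
#' @param a,b single rows of an individual table ([read_individuals()]).
#' @param kin_pairs unordered maternal kin pairs ([read_kin_pairs()]), or
#'   `NULL` for no known kin.
#' @param age_class_window maximum birth-year difference within one age class.
#' @return a one-row `data.frame` with logical columns `same_sex`,
#'   `same_age_class`, `reproductively_active`, `maternal_kin`.
#' @export
score_dyad_attributes <- function(a, b, kin_pairs = NULL, age_class_window = 5) {
  if (is.na(a$sex) || is.na(b$sex)) {
    stop("both individuals must have a recorded sex", call. = FALSE)
  }
  same_sex <- a$sex == b$sex
  if (is.na(a$birth_year) || is.na(b$birth_year)) {
    message(sprintf("dyad %s-%s: missing birth year, age class flagged missing",
                    a$id, b$id))
    same_age <- NA
  } else {
    same_age <- abs(a$birth_year - b$birth_year) <= age_class_window
  }
  oestrous <- function(x) !is.na(x$reproductive_status) && x$reproductive_status == "oestrous"
  repro <- (a$sex == "male" && b$sex == "female" && oestrous(b)) ||
           (b$sex == "male" && a$sex == "female" && oestrous(a))
  data.frame(same_sex = same_sex, same_age_class = same_age,
             reproductively_active = repro,
             maternal_kin = .is_kin(a$id, b$id, kin_pairs))
}

#' Score attributes for every ordered dyad
#'
#' @param individuals individual attribute table.
#' @param kin_pairs unordered maternal kin pairs, or `NULL`.
#' @param age_class_window see [score_dyad_attributes()].
#' @return a `data.frame` with one row per ordered pair of distinct
#'   individuals (`n * (n - 1)` rows), columns `id_a`, `id_b` and the four
#'   attribute flags.
#' @export
dyad_attribute_table <- function(individuals, kin_pairs = NULL, age_class_window = 5) {
  ids <- individuals$id
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      att <- score_dyad_attributes(individuals[i, ], individuals[j, ],
                                   kin_pairs, age_class_window)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(id_a = ids[i], id_b = ids[j], stringsAsFactors = FALSE), att)
    }
  }
  do.call(rbind, rows)
}

#' Dominance ordering from pantgrunt degrees
#'
#' Ranks individuals by received pantgrunts: pantgrunting is directed up the
#' hierarchy, so a higher pantgrunt-given indegree indicates a more dominant
#' individual. Ties are broken by lower pantgrunt outdegree (dominant animals
#' pantgrunt less), then lexicographically by id so the ordering is total and
#' deterministic.
#'
#' @param individuals individual attribute table.
#' @return character vector of ids, most dominant first.
#' @export
dominance_order <- function(individuals) {
  ord <- order(-individuals$pantgrunt_indegree, individuals$pantgrunt_outdegree,
               individuals$id)
  individuals$id[ord]
}

#' Classify the audience of a gesture relative to the signaller
#'
#' Counts, among the individuals within 10 m at the time of a gesture and
#' excluding both the signaller and the recipient, how many were of the same
#' or a different age class as the signaller and of the same or the opposite
#' sex. Audience members missing the relevant attribute are excluded from
#' the affected count (with a message).
#'
#' @param event a single gesture event (one row of a gesture table).
#' @param individuals individual attribute table.
#' @param age_class_window see [score_dyad_attributes()].
#' @return named integer vector with elements `same_age`, `diff_age`,
#'   `same_sex`, `opp_sex`.
#' @export
audience_counts <- function(event, individuals, age_class_window = 5) {
  aud <- setdiff(event$audience_10m_ids[[1]],
                 c(event$signaller_id, event$recipient_id))
  sig <- individuals[match(event$signaller_id, individuals$id), ]
  if (nrow(sig) == 0 || is.na(sig$id)) {
    stop("signaller not found in individual table", call. = FALSE)
  }
  counts <- c(same_age = 0L, diff_age = 0L, same_sex = 0L, opp_sex = 0L)
  for (id in aud) {
    other <- individuals[match(id, individuals$id), ]
    if (is.na(other$id)) {
      message(sprintf("audience member '%s' unknown; excluded from all counts", id))
      next
    }
    if (is.na(sig$birth_year) || is.na(other$birth_year)) {
      message(sprintf("audience member '%s': missing birth year; excluded from age counts", id))
    } else if (abs(sig$birth_year - other$birth_year) <= age_class_window) {
      counts["same_age"] <- counts["same_age"] + 1L
    } else {
      counts["diff_age"] <- counts["diff_age"] + 1L
    }
    if (is.na(other$sex)) {
      message(sprintf("audience member '%s': missing sex; excluded from sex counts", id))
    } else if (other$sex == sig$sex) {
      counts["same_sex"] <- counts["same_sex"] + 1L
    } else {
      counts["opp_sex"] <- counts["opp_sex"] + 1L
    }
  }
  counts
}
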