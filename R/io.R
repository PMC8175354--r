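#' Load a student roster
#'
#' Reads the roster CSV with header columns `id`, `group`, `gender`,
#' `wave1`, `wave2`. `wave1`/`wave2` are participation flags (logical or
#' 0/1): a student kept on the roster but absent from one survey wave is
#' excluded from that wave's node set downstream.
#'
#' @param path path to a delimited text file (comma-separated, header row).
#' @return data frame of class `roster` with columns `id`, `group`,
#'   `gender`, `wave1`, `wave2`.
#' @export
load_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("id", "group", "gender", "wave1", "wave2"), "roster file")
  df$id <- as.character(df$id)
  df$group <- as.character(df$group)
  df$gender <- as.character(df$gender)
  df$wave1 <- as.logical(df$wave1)
  df$wave2 <- as.logical(df$wave2)
  as_roster(df)
}

#' Construct a roster from a data frame
#'
#' @param df data frame with columns `id`, `group`, `gender`, `wave1`, `wave2`.
#' @return the validated data frame with class `roster` prepended.
#' @export
as_roster <- function(df) {
  require_columns(df, c("id", "group", "gender", "wave1", "wave2"), "roster")
  if (anyDuplicated(df$id)) {
    stop_validation("duplicate student id(s): ",
                    paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  participant <- df$wave1 | df$wave2
  if (any(participant & (is.na(df$group) | df$group == ""))) {
    stop_validation("participants must have a non-empty group label")
  }
  if (any(participant & (is.na(df$gender) | df$gender == ""))) {
    stop_validation("participants must have a non-empty gender label")
  }
  rownames(df) <- NULL
  class(df) <- c("roster", "data.frame")
  df
}

#' Load nomination records
#'
#' Reads the nomination edge table (`ego`, `alter`, `wave`, `sign`,
#' `intensity`). Intensity 1 is the inner level ("best friend" / "worst
#' enemy"), intensity 2 the outer level ("friend" / "enemy").
#' Self-nominations are rejected as a validation error; rows referencing ids
#' absent from the roster are dropped with a warning and attached to the
#' result as attribute `"rejected"`.
#'
#' @param path path to a delimited text file (comma-separated, header row).
#' @param roster roster the ids must belong to.
#' @return data frame with columns `ego`, `alter`, `wave`, `sign`,
#'   `intensity`; rejected rows in `attr(, "rejected")`.
#' @export
load_nominations <- function(path, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_nominations(df, roster)
}

#' @rdname load_nominations
#' @param df data frame already in memory with the same columns.
#' @export
as_nominations <- function(df, roster) {
  require_columns(df, c("ego", "alter", "wave", "sign", "intensity"),
                  "nomination table")
  df$ego <- as.character(df$ego)
  df$alter <- as.character(df$alter)
  df$wave <- as.integer(df$wave)
  df$sign <- as.character(df$sign)
  df$intensity <- as.integer(df$intensity)
  if (!all(df$wave %in% c(1L, 2L))) stop_format("wave must be 1 or 2")
  if (!all(df$sign %in% c("positive", "negative"))) {
    stop_format("sign must be 'positive' or 'negative'")
  }
  if (!all(df$intensity %in% c(1L, 2L))) {
    stop_format("intensity must be 1 (inner) or 2 (outer)")
  }
  if (any(df$ego == df$alter)) {
    stop_validation("self-nominations are not allowed (ego == alter)")
  }
  known <- df$ego %in% roster$id & df$alter %in% roster$id
  rejected <- df[!known, , drop = FALSE]
  if (nrow(rejected)) {
    warning(sprintf("%d nomination row(s) reference ids absent from the roster and were rejected",
                    nrow(rejected)), call. = FALSE)
  }
  df <- df[known, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

#' Map raw six-question survey answers to signed two-level nominations
#'
#' The original questionnaire asked three intensity levels per sign; the two
#' lower levels could not be reliably discriminated by respondents and are
#' merged into a single outer level. Questions 1-3 are positive, 4-6
#' negative, ordered from least to most intense within each sign.
#'
#' @details Mapping: Q1 and Q2 (the two lower positive levels) merge to the
#' outer positive level (intensity 2, "friend"); Q3 maps to the inner
#' positive level (intensity 1, "best friend"). Analogously Q4, Q5 merge to
#' the outer negative level ("enemy") and Q6 maps to the inner negative
#' level ("worst enemy").
#'
#' @param df data frame with columns `ego`, `alter`, `wave`, `question`
#'   (integer 1-6).
#' @param roster roster for id validation.
#' @return nomination data frame as from [load_nominations()].
#' @export
merge_question_levels <- function(df, roster) {
  require_columns(df, c("ego", "alter", "wave", "question"), "raw answer table")
  q <- as.integer(df$question)
  if (!all(q %in% 1:6)) stop_format("question must be an integer in 1..6")
  out <- data.frame(
    ego = as.character(df$ego),
    alter = as.character(df$alter),
    wave = as.integer(df$wave),
    sign = ifelse(q <= 3, "positive", "negative"),
    intensity = ifelse(q %in% c(3L, 6L), 1L, 2L),
    stringsAsFactors = FALSE
  )
  as_nominations(out, roster)
}

#' Resolve nomination records into a signed directed network
#'
#' Applies the survey weight-resolution rules for one wave. Within a sign,
#' when the same ordered pair is reported at both intensities the most
#' intense report wins (|w| = 2 beats |w| = 1). When a pair carries both a
#' positive and a negative report, the two resolved signed weights are
#' summed and the link is removed if the sum is zero. All resulting weights
#' lie in {-2, -1, 1, 2}.
#'
#' @param records nomination data frame ([load_nominations()]).
#' @param wave which wave to resolve (1 or 2).
#' @param roster optional roster; when given, the node set is the wave's
#'   participants plus any nominated non-participants (the latter are listed
#'   in attribute `"non_participants"` of the result).
#' @return a [signed_network()].
#' @examples
#' roster <- as_roster(data.frame(id = c("s1", "s2"), group = "A",
#'                                gender = c("F", "M"),
#'                                wave1 = TRUE, wave2 = TRUE))
#' recs <- as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
#'                                   sign = c("positive", "positive"),
#'                                   intensity = c(1, 2)), roster)
#' resolve_weights(recs, wave = 1, roster = roster)$edges  # single +2 edge
#' @export
resolve_weights <- function(records, wave, roster = NULL) {
  stopifnot(wave %in% c(1, 2))
  r <- records[records$wave == wave, , drop = FALSE]
  non_participants <- character()
  if (!is.null(roster)) {
    part <- roster$id[roster[[paste0("wave", wave)]]]
    bad_ego <- setdiff(unique(r$ego), part)
    if (length(bad_ego)) {
      warning(sprintf("%d ego id(s) did not participate in wave %d; their nominations were dropped",
                      length(bad_ego), wave), call. = FALSE)
      r <- r[r$ego %in% part, , drop = FALSE]
    }
    non_participants <- setdiff(unique(r$alter), part)
    nodes <- union(part, non_participants)
  } else {
    nodes <- unique(c(r$ego, r$alter))
  }

  if (nrow(r)) {
    # step 1: within each (pair, sign), keep the most intense report.
    # intensity 1 is the inner ("best friend"/"worst enemy") level = |w| 2.
    mag <- ifelse(r$intensity == 1L, 2L, 1L)
    signed <- ifelse(r$sign == "positive", mag, -mag)
    key <- paste(r$ego, r$alter, r$sign, sep = "\r")
    per_sign <- tapply(signed, key, function(v) v[which.max(abs(v))])
    # step 2: sum the resolved positive and negative weights per pair,
    # dropping zero sums
    ka <- do.call(rbind, strsplit(names(per_sign), "\r", fixed = TRUE))
    pair <- paste(ka[, 1], ka[, 2], sep = "\r")
    total <- tapply(as.numeric(per_sign), pair, sum)
    keep <- total != 0
    if (any(keep)) {
      pk <- do.call(rbind, strsplit(names(total)[keep], "\r", fixed = TRUE))
      edges <- data.frame(from = pk[, 1], to = pk[, 2],
                          weight = as.numeric(total[keep]),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(from = character(), to = character(),
                          weight = numeric())
    }
  } else {
    edges <- data.frame(from = character(), to = character(), weight = numeric())
  }
  # canonical order so that the result is invariant to input row order
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), ]
  net <- signed_network(sort(nodes), edges)
  attr(net, "non_participants") <- sort(non_participants)
  net
}
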