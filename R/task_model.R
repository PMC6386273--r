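#' Define a task model
#'
#' A task model partitions a set of actions (basic action concepts, BACs)
#' into activities. Each activity is either *ordered* — its actions must be
#' executed in the listed sequence — or *unordered* — any permutation of its
#' actions is correct. Correct action sequences never span activities. An
#' optional `sequences` field replaces the activity-derived enumeration with
#' an explicit list of correct sequences, for tasks whose correct sequences
#' do not decompose into single-activity runs.
#'
#' @param actions data.frame with columns `id` (unique positive integers) and
#'   `label` (free text).
#' @param activities list of activities, each a list with fields `id`, `name`,
#'   `ordered` (logical) and `action_ids` (integer vector; order meaningful
#'   iff `ordered`). The `action_ids` must be disjoint across activities and
#'   jointly cover every action exactly once.
#' @param sequences optional list of integer vectors, each a complete correct
#'   action sequence. When supplied it overrides the activity-derived
#'   enumeration of correct sequences.
#' @return an object of class `sdam_task`.
#' @seealso [kiosk_task()] for the built-in 15-action example task,
#'   [is_valid_prefix()], [follow_ups()], [make_situation()].
#' @export
sdam_task <- function(actions, activities, sequences = NULL) {
  actions <- as.data.frame(actions)
  if (!all(c("id", "label") %in% names(actions)))
    stop("`actions` needs columns `id` and `label`", call. = FALSE)
  ids <- as.integer(actions$id)
  if (anyNA(ids) || any(ids < 1L))
    stop("action ids must be positive integers", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate action id: ", ids[duplicated(ids)][1L], call. = FALSE)
  actions$id <- ids

  seen <- integer(0)
  for (act in activities) {
    for (f in c("id", "name", "ordered", "action_ids"))
      if (is.null(act[[f]]))
        stop("activity missing field `", f, "`", call. = FALSE)
    aid <- as.integer(act$action_ids)
    if (length(aid) < 1L)
      stop("activity ", act$id, " has no actions", call. = FALSE)
    bad <- setdiff(aid, ids)
    if (length(bad))
      stop("activity ", act$id, " references unknown action id: ", bad[1L],
           call. = FALSE)
    dup <- intersect(aid, seen)
    if (length(dup))
      stop("action id ", dup[1L], " belongs to more than one activity",
           call. = FALSE)
    seen <- c(seen, aid)
  }
  orphan <- setdiff(ids, seen)
  if (length(orphan))
    stop("action id ", orphan[1L], " belongs to no activity", call. = FALSE)

  activities <- lapply(activities, function(a)
    list(id = as.integer(a$id), name = as.character(a$name),
         ordered = isTRUE(a$ordered), action_ids = as.integer(a$action_ids)))

  if (!is.null(sequences)) {
    sequences <- lapply(sequences, as.integer)
    for (s in sequences) {
      bad <- setdiff(s, ids)
      if (length(bad))
        stop("sequence references unknown action id: ", bad[1L], call. = FALSE)
      if (anyDuplicated(s))
        stop("sequence repeats action id: ", s[duplicated(s)][1L],
             call. = FALSE)
    }
  }

  actions$activity_id <- vapply(actions$id, function(i) {
    for (a in activities) if (i %in% a$action_ids) return(a$id)
    NA_integer_
  }, integer(1))

  structure(list(actions = actions, activities = activities,
                 sequences = sequences),
            class = "sdam_task")
}

#' @export
print.sdam_task <- function(x, ...) {
  cat("SDA-M task model:", nrow(x$actions), "actions,",
      length(x$activities), "activities\n")
  for (a in x$activities)
    cat(sprintf("  [%d] %s (%s): %s\n", a$id, a$name,
                if (a$ordered) "ordered" else "unordered",
                paste(a$action_ids, collapse = if (a$ordered) " > " else ", ")))
  if (!is.null(x$sequences))
    cat("  explicit correct sequences:", length(x$sequences), "\n")
  invisible(x)
}

#' @export
format.sdam_task <- function(x, ...) {
  paste0("<sdam_task: ", nrow(x$actions), " actions, ",
         length(x$activities), " activities>")
}

task_action_ids <- function(task) task$actions$id

task_activity_of <- function(task, id) {
  task$actions$activity_id[match(id, task$actions$id)]
}

task_activity <- function(task, activity_id) {
  for (a in task$activities) if (a$id == activity_id) return(a)
  stop("unknown activity id: ", activity_id, call. = FALSE)
}

check_known_ids <- function(task, seq) {
  bad <- setdiff(seq, task_action_ids(task))
  if (length(bad))
    stop("unknown action id: ", bad[1L], call. = FALSE)
  if (anyDuplicated(seq))
    stop("duplicate action id in sequence: ", seq[duplicated(seq)][1L],
         call. = FALSE)
}

#' Test whether an executed sequence is a valid prefix of a correct sequence
#'
#' A correct sequence contains actions from a single activity only and, for
#' an ordered activity, in its fixed order. With an explicit `sequences`
#' field the test is membership as a prefix of one of the listed sequences.
#'
#' @param task an [sdam_task()].
#' @param seq integer vector of executed action ids, oldest first.
#' @return TRUE or FALSE. Unknown or repeated ids are an error, not FALSE:
#'   they indicate malformed input rather than an incorrect execution.
#' @export
is_valid_prefix <- function(task, seq) {
  seq <- as.integer(seq)
  check_known_ids(task, seq)
  if (length(seq) == 0L) return(TRUE)
  if (!is.null(task$sequences)) {
    for (s in task$sequences)
      if (length(s) >= length(seq) && identical(s[seq_along(seq)], seq))
        return(TRUE)
    return(FALSE)
  }
  acts <- task_activity_of(task, seq)
  if (length(unique(acts)) != 1L) return(FALSE)
  a <- task_activity(task, acts[1L])
  if (!a$ordered) return(TRUE)  # same activity, no repeats: any subset order-free
  identical(a$action_ids[seq_along(seq)], seq)
}

#' Correct immediate follow-up actions of an executed prefix
#'
#' Returns the set `C_S` of actions that correctly extend the executed
#' prefix by one step: for an ordered activity the single next action of its
#' fixed sequence, for an unordered activity all of its remaining actions,
#' and with explicit `sequences` the union of next elements over all listed
#' sequences extending the prefix. The empty set means the sequence is
#' complete.
#'
#' @inheritParams is_valid_prefix
#' @return integer vector of action ids (possibly empty), sorted.
#' @export
follow_ups <- function(task, seq) {
  seq <- as.integer(seq)
  if (!is_valid_prefix(task, seq))
    stop("`seq` is not a valid prefix of any correct sequence", call. = FALSE)
  if (!is.null(task$sequences)) {
    nxt <- integer(0)
    for (s in task$sequences)
      if (length(s) > length(seq) && identical(s[seq_along(seq)], seq))
        nxt <- c(nxt, s[length(seq) + 1L])
    return(sort(unique(nxt)))
  }
  if (length(seq) == 0L)
    stop("empty prefix: every action that starts a correct sequence would ",
         "follow; supply at least one executed action", call. = FALSE)
  a <- task_activity(task, task_activity_of(task, seq[1L]))
  if (a$ordered) {
    if (length(seq) < length(a$action_ids))
      return(a$action_ids[length(seq) + 1L])
    return(integer(0))
  }
  sort(setdiff(a$action_ids, seq))
}

#' Build a prediction situation from an executed action prefix
#'
#' Packages an executed prefix into the quantities the prediction algorithms
#' operate on: the most recent action `a_j`, the second-most recent `a_i`
#' (absent when only one action has been executed), the correct follow-up
#' set `C_S`, and the candidate set (all actions except `a_i` and `a_j` —
#' note that *less* recent executed actions remain candidates).
#'
#' Predicting the very first action of a task is unsupported: both
#' algorithms require a most recent action, so an empty prefix is an error.
#' A completed sequence (empty `C_S`) is also an error — there is nothing
#' left to predict.
#'
#' @inheritParams is_valid_prefix
#' @param executed integer vector of executed action ids, oldest first.
#' @return an object of class `sdam_situation`: a list with fields
#'   `executed`, `a_i` (NA if absent), `a_j`, `C_S`, `candidates`.
#' @export
make_situation <- function(task, executed) {
  executed <- as.integer(executed)
  if (length(executed) == 0L)
    stop("empty prefix: no first-action prediction is defined", call. = FALSE)
  if (!is_valid_prefix(task, executed))
    stop("`executed` is not a valid prefix of any correct sequence",
         call. = FALSE)
  C_S <- follow_ups(task, executed)
  if (length(C_S) == 0L)
    stop("sequence is complete: nothing to predict", call. = FALSE)
  n <- length(executed)
  a_j <- executed[n]
  a_i <- if (n >= 2L) executed[n - 1L] else NA_integer_
  candidates <- sort(setdiff(task_action_ids(task),
                             c(a_j, if (!is.na(a_i)) a_i)))
  structure(list(executed = executed, a_i = a_i, a_j = a_j,
                 C_S = C_S, candidates = candidates),
            class = "sdam_situation")
}

#' @export
print.sdam_situation <- function(x, ...) {
  cat("Situation: executed (", paste(x$executed, collapse = ", "), ")\n",
      "  a_j = ", x$a_j,
      if (!is.na(x$a_i)) paste0(", a_i = ", x$a_i) else ", a_i absent",
      "\n  correct follow-ups: {", paste(x$C_S, collapse = ", "), "}\n",
      "  candidates: ", length(x$candidates), " actions\n", sep = "")
  invisible(x)
}

#' Enumerate all complete correct sequences of a task
#'
#' Ordered activities contribute their single fixed sequence; unordered
#' activities contribute every permutation of their actions. Intended for
#' small tasks (permutations grow factorially); the built-in kiosk task's
#' largest unordered activity has 5 actions (120 sequences).
#'
#' @inheritParams is_valid_prefix
#' @return list of integer vectors.
#' @export
enumerate_sequences <- function(task) {
  if (!is.null(task$sequences)) return(task$sequences)
  out <- list()
  for (a in task$activities) {
    if (a$ordered) {
      out <- c(out, list(a$action_ids))
    } else {
      out <- c(out, lapply(permutations_of(length(a$action_ids)),
                           function(p) a$action_ids[p]))
    }
  }
  out
}

permutations_of <- function(m) {
  if (m == 1L) return(list(1L))
  sub <- permutations_of(m - 1L)
  out <- vector("list", m * length(sub))
  k <- 0L
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}
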