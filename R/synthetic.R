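#' The built-in kiosk task model
#'
#' A 15-action, 4-activity task describing the preparation, customer
#' service, wrap-up and laundry duties of running a small kiosk. Customer
#' service and laundry are ordered (their actions must run in sequence);
#' preparation and wrap-up are unordered (any permutation is correct).
#' Correct sequences never mix activities.
#'
#' @return an [sdam_task()] with action ids 1-15.
#' @export
kiosk_task <- function() {
  actions <- data.frame(
    id = 1:15,
    label = c(
      "Refill cutlery cart",
      "Fill in coffee beans and cocoa",
      "Refill fridge with drinks",
      "Put plate for rolls in place",
      "Allocate cart for dirty dishes",
      "Welcome the customer and take the order",
      "Prepare coffee and cocoa",
      "Serve drinks and food",
      "Take the money",
      "Wash the dishes and start the dishwasher",
      "Clean the glass pane of the refrigerator",
      "Clean the coffee machine",
      "Wipe the surfaces",
      "Wash the laundry",
      "Hang up and iron the laundry"
    ),
    stringsAsFactors = FALSE
  )
  activities <- list(
    list(id = 1L, name = "Kiosk preparation", ordered = FALSE,
         action_ids = 1:5),
    list(id = 2L, name = "Kiosk customer service", ordered = TRUE,
         action_ids = 6:9),
    list(id = 3L, name = "Kiosk wrap-up", ordered = FALSE,
         action_ids = 10:13),
    list(id = 4L, name = "Laundry", ordered = TRUE, action_ids = 14:15)
  )
  sdam_task(actions, activities)
}

#' Ideal association structure of a task
#'
#' The association pattern a perfectly structured memory representation
#' would show: actions of the same *ordered* activity are associated iff
#' adjacent in the fixed sequence (each action with its immediate
#' predecessor and successor); actions of the same *unordered* activity are
#' all pairwise associated by default (`unordered = "all"`, since any of
#' them may immediately precede or follow any other), or adjacency in the
#' listed order with `unordered = "adjacent"`; actions of different
#' activities are never associated.
#'
#' @param task an [sdam_task()].
#' @param unordered association rule within unordered activities.
#' @return symmetric 0/1 matrix with zero diagonal, dimnames = action ids.
#' @export
ideal_associations <- function(task, unordered = c("all", "adjacent")) {
  unordered <- match.arg(unordered)
  ids <- task_action_ids(task)
  M <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in task$activities) {
    aid <- as.character(a$action_ids)
    if (a$ordered || unordered == "adjacent") {
      for (k in seq_len(length(aid) - 1L)) {
        M[aid[k], aid[k + 1L]] <- 1L
        M[aid[k + 1L], aid[k]] <- 1L
      }
    } else {
      M[aid, aid] <- 1L
      M[cbind(aid, aid)] <- 0L
    }
  }
  M
}

#' Simulate one participant's split-procedure responses
#'
#' Draws the participant's verdict for every directed (target, compared)
#' pair: the ideal association (see [ideal_associations()]) flipped
#' independently with probability `epsilon`. The flip probability models
#' the participant's distance from a perfectly structured task
#' representation: `epsilon = 0` is an ideal expert, values near 0.5 are
#' indistinguishable from guessing. The two directions of a pair are
#' flipped independently — the split procedure asks them separately.
#'
#' @param task an [sdam_task()].
#' @param epsilon flip probability; values in \code{[0, 1]} are accepted so
#'   adversarial (systematically inverted, epsilon > 0.5) respondents can be
#'   simulated.
#' @param participant_id identifier stored in the dataset.
#' @param seed integer seed; the dataset is reproducible given
#'   (seed, task, epsilon). NULL uses the current RNG state.
#' @param unordered passed to [ideal_associations()].
#' @return an [sdam_splits()] dataset.
#' @export
simulate_split <- function(task, epsilon, participant_id = 1L, seed = NULL,
                           unordered = c("all", "adjacent")) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  ideal <- ideal_associations(task, match.arg(unordered))
  ids <- task_action_ids(task)
  pairs <- expand.grid(target_id = ids, compared_id = ids)
  pairs <- pairs[pairs$target_id != pairs$compared_id, ]
  draw <- function() {
    flip <- stats::runif(nrow(pairs)) < epsilon
    assoc <- ideal[cbind(as.character(pairs$target_id),
                         as.character(pairs$compared_id))] == 1L
    ifelse(xor(assoc, flip), 1L, -1L)
  }
  verdict <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  sdam_splits(data.frame(participant_id = participant_id,
                         target_id = pairs$target_id,
                         compared_id = pairs$compared_id,
                         verdict = verdict), task)
}

#' Generate random test-case situations
#'
#' Each case is a correct, incomplete prefix: an activity is picked
#' uniformly (balancing activities against the factorially larger number of
#' sequences in big unordered ones), a correct ordering of it is drawn (the
#' fixed sequence if ordered, a uniform permutation otherwise), and the
#' prefix is cut at a uniform length between 1 and the activity size minus
#' one — so every case has a non-empty follow-up set.
#'
#' @param task an [sdam_task()].
#' @param n_cases number of cases, >= 1.
#' @param seed integer seed; NULL uses the current RNG state.
#' @return data.frame with columns `case_id` and `executed` (space-separated
#'   action ids).
#' @export
generate_test_cases <- function(task, n_cases, seed = NULL) {
  stopifnot(n_cases >= 1)
  draw <- function() {
    out <- character(n_cases)
    eligible <- Filter(function(a) length(a$action_ids) >= 2L,
                       task$activities)
    if (length(eligible) == 0L)
      stop("no activity with at least 2 actions", call. = FALSE)
    for (k in seq_len(n_cases)) {
      a <- eligible[[sample.int(length(eligible), 1L)]]
      ord <- if (a$ordered || length(a$action_ids) == 1L) a$action_ids
             else sample(a$action_ids)
      len <- sample.int(length(ord) - 1L, 1L)
      out[k] <- paste(ord[seq_len(len)], collapse = " ")
    }
    out
  }
  executed <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(case_id = seq_len(n_cases), executed = executed,
             stringsAsFactors = FALSE)
}
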