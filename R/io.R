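#' Read and write task models as JSON
#'
#' The task schema has `actions` (objects with `id`, `label`), `activities`
#' (objects with `id`, `name`, `ordered`, `action_ids`) and an optional
#' `sequences` array of id arrays. `read_task("builtin:kiosk")` returns the
#' built-in [kiosk_task()].
#'
#' @param path file path, or the string `"builtin:kiosk"`.
#' @return an [sdam_task()].
#' @export
read_task <- function(path) {
  if (identical(path, "builtin:kiosk")) return(kiosk_task())
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$actions) || is.null(x$activities))
    stop("task JSON needs `actions` and `activities`", call. = FALSE)
  actions <- data.frame(
    id = vapply(x$actions, function(a) {
      if (is.null(a$id)) stop("action missing `id`", call. = FALSE)
      as.integer(a$id)
    }, integer(1)),
    label = vapply(x$actions, function(a) as.character(a$label %||% ""),
                   character(1)),
    stringsAsFactors = FALSE
  )
  activities <- lapply(x$activities, function(a) {
    if (is.null(a$id)) stop("activity missing `id`", call. = FALSE)
    list(id = as.integer(a$id), name = as.character(a$name %||% ""),
         ordered = isTRUE(a$ordered),
         action_ids = as.integer(unlist(a$action_ids)))
  })
  sequences <- if (!is.null(x$sequences))
    lapply(x$sequences, function(s) as.integer(unlist(s)))
  sdam_task(actions, activities, sequences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_task
#' @param task an [sdam_task()].
#' @export
write_task <- function(task, path) {
  x <- list(
    actions = lapply(seq_len(nrow(task$actions)), function(i)
      list(id = task$actions$id[i], label = task$actions$label[i])),
    activities = task$activities
  )
  if (!is.null(task$sequences)) x$sequences <- task$sequences
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write split-procedure judgment CSVs
#'
#' Columns `participant_id,target_id,compared_id,verdict`, verdict in
#' \{1, -1\}; UTF-8, comma-separated, header row.
#'
#' @param path CSV path.
#' @param task an [sdam_task()] used for completeness validation.
#' @return an [sdam_splits()] (possibly covering several participants).
#' @export
read_splits <- function(path, task) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sdam_splits(x, task)
}

#' @rdname read_splits
#' @param splits an [sdam_splits()] data.frame.
#' @export
write_splits <- function(splits, path) {
  utils::write.csv(as.data.frame(splits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write dense matrices with an action-id header row and column
#'
#' Values are written with 17 significant digits, so a write/read cycle
#' reproduces doubles exactly.
#'
#' @param M numeric matrix with dimnames.
#' @param path CSV path.
#' @export
write_matrix_csv <- function(M, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(M)), collapse = ","), con)
  for (i in seq_len(nrow(M)))
    writeLines(paste(c(rownames(M)[i],
                       sprintf("%.17g", M[i, ])), collapse = ","), con)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(x[[1L]])
  M <- as.matrix(x[, -1L, drop = FALSE])
  rownames(M) <- ids
  storage.mode(M) <- "double"
  M
}

#' Read and write test-case CSVs
#'
#' Columns `case_id,executed`; `executed` holds the prefix as
#' space-separated action ids.
#'
#' @param path CSV path.
#' @param task optional [sdam_task()]; when given, every case is validated
#'   as a correct incomplete prefix.
#' @export
read_cases <- function(path, task = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "executed") %in% names(x)))
    stop("cases CSV needs columns `case_id` and `executed`", call. = FALSE)
  x$executed <- as.character(x$executed)
  if (!is.null(task))
    for (k in seq_len(nrow(x)))
      make_situation(task, as.integer(strsplit(x$executed[k], "[ ;]+")[[1L]]))
  x
}

#' @rdname read_cases
#' @param cases data.frame with `case_id` and `executed`.
#' @export
write_cases <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rater panel CSV into a rater x case matrix
#'
#' Long format, columns `case_id,rater_id,judgment` with judgment in
#' \{0, 1\}.
#'
#' @param path CSV path.
#' @return binary matrix, rownames = rater ids, colnames = case ids.
#' @export
read_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "rater_id", "judgment")
  if (!all(need %in% names(x)))
    stop("panel CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(x$judgment %in% c(0, 1)))
    stop("judgment must be 0 or 1", call. = FALSE)
  raters <- sort(unique(x$rater_id))
  cases <- unique(x$case_id)
  M <- matrix(NA_real_, length(raters), length(cases),
              dimnames = list(raters, cases))
  M[cbind(match(x$rater_id, raters), match(x$case_id, cases))] <- x$judgment
  if (anyNA(M))
    stop("panel is incomplete: every rater must judge every case",
         call. = FALSE)
  M
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys (all optional, shown with defaults):
#' ```yaml
#' matrices: {self_column: self_max, sd: population}
#' caspa:    {s: 0.4, threshold: default}   # default | informed | <number>
#' clustering: {d_crit: ~}
#' seed: 1
#' ```
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    matrices = list(self_column = "self_max", sd = "population"),
    caspa = list(s = 0.4, threshold = "default"),
    clustering = list(d_crit = NULL),
    seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge_checked(defaults, user, "config")
}

merge_checked <- function(defaults, user, where) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_checked(defaults[[k]], user[[k]], paste0(where, "$", k))
    else user[[k]]
  }
  defaults
}

#' Run the end-to-end pipeline
#'
#' Simulate (or load) split data, build each participant's Z/R/D matrices,
#' cluster and export dendrograms, predict over the test cases with AMPA and
#' CASPA, and write predictions plus a JSON report. Each case is assessed
#' against a participant: either the `participant_id` column of `cases`, or
#' a seeded random assignment (mirroring a study design that pairs each
#' fictitious execution prefix with a random subject's memory structure).
#'
#' @param task an [sdam_task()] or a path accepted by [read_task()].
#' @param splits an [sdam_splits()] data.frame (any number of participants)
#'   or a CSV path.
#' @param cases data.frame with `case_id`, `executed` (and optionally
#'   `participant_id`), or a CSV path.
#' @param config list from [read_config()] (or NULL for defaults).
#' @param out_dir optional output directory; when given, writes
#'   `matrices_<pid>_{Z,R,D}.csv`, `dendrogram_<pid>.nwk`,
#'   `predictions.csv` and `report.json`.
#' @return list with `predictions` (data.frame), `bundles`, `dendrograms`,
#'   `informed_threshold`, `config`, `log`.
#' @export
run_pipeline <- function(task, splits, cases, config = NULL,
                         out_dir = NULL) {
  if (is.character(task)) task <- read_task(task)
  cfg <- if (is.null(config)) read_config() else config
  if (is.character(splits)) splits <- read_splits(splits, task)
  if (!inherits(splits, "sdam_splits")) splits <- sdam_splits(splits, task)
  if (is.character(cases)) cases <- read_cases(cases, task)

  pids <- sort(unique(splits$participant_id))
  bundles <- lapply(pids, function(p)
    build_matrices(splits[splits$participant_id == p, , drop = FALSE],
                   task,
                   self_column = cfg$matrices$self_column,
                   sd = cfg$matrices$sd))
  names(bundles) <- as.character(pids)
  dendros <- lapply(bundles, function(b) average_linkage(b$D))

  if (is.null(cases$participant_id)) {
    cases$participant_id <- withr::with_seed(
      cfg$seed, sample(pids, nrow(cases), replace = TRUE))
  }

  am <- integer(nrow(cases))
  ps <- numeric(nrow(cases))
  for (k in seq_len(nrow(cases))) {
    sit <- make_situation(
      task, as.integer(strsplit(as.character(cases$executed[k]),
                                "[ ;]+")[[1L]]))
    b <- bundles[[as.character(cases$participant_id[k])]]
    am[k] <- ampa(b, sit)$competent
    ps[k] <- caspa_probability(b, sit, s = cfg$caspa$s)
  }
  thr_informed <- informed_threshold(ps)
  thr <- switch(as.character(cfg$caspa$threshold),
                default = 0.5,
                informed = thr_informed,
                as.numeric(cfg$caspa$threshold))
  predictions <- data.frame(
    case_id = cases$case_id,
    participant_id = cases$participant_id,
    ampa = am,
    caspa_p = ps,
    caspa_default = binarize(ps, 0.5),
    caspa_informed = binarize(ps, thr_informed),
    caspa_decision = binarize(ps, thr),
    stringsAsFactors = FALSE
  )

  log <- list(
    package_version = as.character(utils::packageVersion("caspa")),
    n_participants = length(pids),
    n_cases = nrow(cases),
    conventions = cfg$matrices,
    caspa = list(s = cfg$caspa$s, threshold_mode = cfg$caspa$threshold,
                 threshold_value = thr,
                 informed_threshold = thr_informed),
    seed = cfg$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in names(bundles)) {
      b <- bundles[[p]]
      write_matrix_csv(b$Z, file.path(out_dir, paste0("matrices_", p, "_Z.csv")))
      write_matrix_csv(b$R, file.path(out_dir, paste0("matrices_", p, "_R.csv")))
      write_matrix_csv(b$D, file.path(out_dir, paste0("matrices_", p, "_D.csv")))
      writeLines(to_newick(dendros[[p]]),
                 file.path(out_dir, paste0("dendrogram_", p, ".nwk")))
    }
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(predictions = predictions, bundles = bundles, dendrograms = dendros,
       informed_threshold = thr_informed, config = cfg, log = log)
}
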