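#' Parse a scripted interactive session
#'
#' The replay format stands in for GUI interaction: a plain-text list of
#' marker-graph edits and feedback marks, grouped into iterations by
#' `---` separator lines. Supported actions (one per line):
#' \describe{
#'   \item{`add z y x [segment_id]`}{add a guidance seed, optionally into
#'     an existing segment}
#'   \item{`merge a b`}{merge two segments}
#'   \item{`delete a`}{delete a segment}
#'   \item{`confirm a`}{mark a segment correct (positive feedback)}
#'   \item{`correct a`}{mark a segment as corrected (negative feedback)}
#' }
#' Lines starting with `#` are comments.
#'
#' @param lines character vector of script lines, or a file path.
#' @return A `session_script`: list of iterations, each a list of action
#'   lists with `type` and arguments.
#' @export
parse_session_script <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  iters <- list()
  cur <- list()
  flush <- function() {
    iters[[length(iters) + 1L]] <<- cur
    cur <<- list()
  }
  for (ln in lines) {
    if (ln == "---") {
      flush()
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    type <- parts[1]
    args <- as.numeric(parts[-1])
    act <- switch(type,
      add = list(type = "add", p = args[1:3],
                 target = if (length(args) >= 4) as.integer(args[4]) else NULL),
      merge = list(type = "merge", a = as.integer(args[1]),
                   b = as.integer(args[2])),
      delete = list(type = "delete", a = as.integer(args[1])),
      confirm = list(type = "confirm", a = as.integer(args[1])),
      correct = list(type = "correct", a = as.integer(args[1])),
      stop("unknown session action: ", type)
    )
    cur[[length(cur) + 1L]] <- act
  }
  if (length(cur) > 0L || length(iters) == 0L) flush()
  structure(iters, class = "session_script")
}

#' Build a session script from action lists
#'
#' Programmatic alternative to [parse_session_script()]: pass one list of
#' actions per iteration, e.g.
#' `session_script(list(list(type = "merge", a = 4, b = 7)))`.
#'
#' @param ... one list of action lists per iteration.
#' @export
session_script <- function(...) {
  structure(list(...), class = "session_script")
}

apply_session_action <- function(graph, feedback, act, it, ai) {
  ctx <- sprintf(" (iteration %d, action %d)", it, ai)
  tryCatch(
    switch(act$type,
      add = list(graph = add_seed(graph, act$p, act$target),
                 feedback = feedback),
      merge = list(graph = merge_segments(graph, act$a, act$b),
                   feedback = feedback),
      delete = list(graph = delete_segment(graph, act$a),
                    feedback = feedback),
      confirm = list(graph = graph, feedback = user_feedback(
        confirmed = union(feedback$confirmed, act$a),
        corrected = setdiff(feedback$corrected, act$a))),
      correct = list(graph = graph, feedback = user_feedback(
        confirmed = setdiff(feedback$confirmed, act$a),
        corrected = union(feedback$corrected, act$a))),
      stop("unknown action type: ", act$type)
    ),
    error = function(e) stop(conditionMessage(e), ctx, call. = FALSE)
  )
}

#' Derive a correction script from ground truth
#'
#' Builds the session script an ideal user would follow given a
#' segmentation and its ground truth: candidate segments whose majority
#' overlap lies in the same truth cell are merged (fixing splits), and
#' truth cells not claimed by any candidate get a fresh seed at their
#' inner point (fixing merges/missed cells). Corrections are triaged the
#' way a user would work: sorted by the affected truth cell's F-measure
#' deficit and distributed over the iterations worst-half first, so the
#' bulk of the improvement lands in the first iteration.
#'
#' @param result a `segmentation_result`.
#' @param truth ground-truth [label_map()].
#' @param iterations number of script iterations (default 3; empty
#'   iterations are appended if there are fewer corrections).
#' @return A `session_script`.
#' @export
script_corrections_from_truth <- function(result, truth, iterations = 3L) {
  cl <- result$label_map$labels
  tl <- truth$labels
  cand <- cell_ids(result$label_map)
  ev <- match_and_score(result$label_map, truth)
  f_of <- setNames(ev$F, ev$truth_id)
  # majority truth cell per candidate segment
  maj <- vapply(cand, function(id) {
    ov <- table(tl[cl == id])
    ov <- ov[as.integer(names(ov)) >= 2L]
    if (length(ov) == 0L) NA_integer_ else as.integer(names(ov)[which.max(ov)])
  }, 0L)
  actions <- list()
  deficit <- numeric(0)
  for (tid in unique(maj[!is.na(maj)])) {
    grp <- cand[!is.na(maj) & maj == tid]
    if (length(grp) > 1L) {
      grp <- sort(grp)
      for (b in grp[-1]) {
        actions[[length(actions) + 1L]] <- list(type = "merge", a = grp[1],
                                                b = b)
        deficit <- c(deficit, 1 - f_of[as.character(tid)])
      }
    }
  }
  missing <- setdiff(cell_ids(label_map(tl)), maj)
  for (tid in missing) {
    actions[[length(actions) + 1L]] <-
      list(type = "add", p = segment_inner_point(tl, tid), target = NULL)
    deficit <- c(deficit, 1 - f_of[as.character(tid)])
  }
  ord <- order(-deficit)
  iters <- vector("list", iterations)
  pos <- 1L
  remaining <- length(ord)
  for (i in seq_len(iterations)) {
    take <- if (i == iterations) remaining else ceiling(remaining / 2)
    iters[[i]] <- actions[ord[seq_len(take) + pos - 1L]]
    pos <- pos + take
    remaining <- remaining - take
    if (remaining <= 0L) break
  }
  for (i in seq_len(iterations)) if (is.null(iters[[i]])) iters[[i]] <- list()
  do.call(session_script, iters)
}

#' Replay a scripted interactive segmentation session
#'
#' Runs the initial segmentation, then applies each iteration's graph
#' edits and re-segments, recomputing the cellness evaluation with the
#' feedback accumulated so far. With ground truth supplied, the mean
#' per-cell F-measure is recorded per iteration. An empty script performs
#' a single iteration identical to a plain segmentation. Replays are
#' fully deterministic.
#'
#' @param volume an [intensity_volume()].
#' @param graph initial [marker_graph()] (e.g. from nuclei seeds).
#' @param script a `session_script` (default: empty).
#' @param truth optional ground-truth [label_map()].
#' @param cellness compute a [cellness_report()] per iteration (default
#'   TRUE; disable for speed).
#' @param ... passed to [run_iteration()].
#' @return A `session_replay`: list with `results` (one
#'   `segmentation_result` per iteration, the initial one first),
#'   `reports` (cellness per iteration or `NULL`s), `mean_f` (numeric
#'   vector or `NULL`), `feedback` (final accumulated feedback).
#' @export
replay_session <- function(volume, graph, script = session_script(),
                           truth = NULL, cellness = TRUE, ...) {
  feedback <- user_feedback()
  results <- list()
  reports <- list()
  fscores <- numeric(0)
  evaluate <- function(res, fb) {
    results[[length(results) + 1L]] <<- res
    reports[[length(reports) + 1L]] <<-
      if (cellness) cellness_report(volume, res$label_map, fb) else NULL
    if (!is.null(truth))
      fscores[length(fscores) + 1L] <<-
        mean_f(match_and_score(res$label_map, truth))
  }
  res <- run_iteration(volume, graph, iteration = 0L,
                       provenance = "initial", ...)
  evaluate(res, feedback)
  empty <- length(script) == 1L && length(script[[1]]) == 0L
  if (!empty) {
    for (it in seq_along(script)) {
      for (ai in seq_along(script[[it]])) {
        st <- apply_session_action(graph, feedback, script[[it]][[ai]],
                                   it, ai)
        graph <- st$graph
        feedback <- st$feedback
      }
      res <- run_iteration(volume, graph, iteration = it,
                           provenance = "user_corrected", ...)
      evaluate(res, feedback)
    }
  }
  structure(list(results = results, reports = reports,
                 mean_f = if (is.null(truth)) NULL else fscores,
                 feedback = feedback),
            class = "session_replay")
}

#' @export
print.session_replay <- function(x, ...) {
  cat(sprintf("session_replay: %d iteration(s)", length(x$results)))
  if (!is.null(x$mean_f))
    cat(sprintf(", mean F: %s", paste(sprintf("%.4f", x$mean_f),
                                      collapse = " -> ")))
  cat("\n")
  invisible(x)
}
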