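#' Define a four-element looped key sequence
#'
#' A motor sequence task presents a short fixed sequence of keys that is
#' executed in a loop: after the last element the target wraps around to the
#' first. The sequence has exactly four elements and each key identifier is
#' unique, so any pressed in-sequence key has an unambiguous position.
#'
#' @param keys character vector of exactly 4 unique key identifiers, in target
#'   order. Identifiers are opaque strings; a mapping table may bind MIDI note
#'   numbers or response-pad button ids to them upstream.
#' @param hands optional character vector of hand/finger labels parallel to
#'   `keys` (e.g. `"right ring"`), documentation only.
#' @return An object of class `"sequence_spec"`.
#' @examples
#' piano_seq <- sequence_spec(c("d4", "a3", "g3", "c3"),
#'                            c("right ring", "left middle", "right thumb", "left thumb"))
#' @export
sequence_spec <- function(keys, hands = NULL) {
  keys <- as.character(keys)
  if (length(keys) != 4L)
    stop("a sequence spec must have exactly 4 elements, got ", length(keys))
  if (anyDuplicated(keys))
    stop("key identifiers must be unique within the sequence: ",
         paste(keys[duplicated(keys)], collapse = ", "))
  if (any(is.na(keys)) || any(!nzchar(keys)))
    stop("key identifiers must be non-missing, non-empty strings")
  if (!is.null(hands)) {
    hands <- as.character(hands)
    if (length(hands) != length(keys))
      stop("'hands' must be parallel to 'keys'")
  }
  structure(list(keys = keys, hands = hands), class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("Looped key sequence:", paste(x$keys, collapse = " -> "), "(wraps)\n")
  if (!is.null(x$hands))
    cat("Fingering:          ", paste(x$hands, collapse = " -> "), "\n")
  invisible(x)
}

# Pointer automaton over one trial's ordered presses.
#
# The scorer walks the looped sequence with a pointer p (0-based position of
# the next expected key):
#   * press == seq[p]        -> correct, p <- (p + 1) mod 4
#   * press not in seq       -> wrong_key, p unchanged
#   * press in seq, != seq[p]-> wrong_order, p resynchronizes to the position
#                               AFTER the pressed key, (j + 1) mod 4,
#                               treating the slip as a skip so one error does
#                               not cascade.
score_keys <- function(keys, seq_keys) {
  pos <- match(keys, seq_keys)  # NA -> not in sequence
  correct <- 0L; wrong_key <- 0L; wrong_order <- 0L
  p <- 1L
  for (i in seq_along(pos)) {
    j <- pos[i]
    if (is.na(j)) {
      wrong_key <- wrong_key + 1L
    } else if (j == p) {
      correct <- correct + 1L
      p <- (p %% 4L) + 1L
    } else {
      wrong_order <- wrong_order + 1L
      p <- (j %% 4L) + 1L
    }
  }
  c(correct = correct, wrong_key = wrong_key, wrong_order = wrong_order)
}

#' Score one trial of key presses against a looped sequence
#'
#' Classifies every press as correct, *wrong key* (a key that is not part of
#' the sequence) or *wrong order* (an in-sequence key pressed out of turn),
#' and returns the trial's performance (number of correct presses), error
#' counts and error rate (errors divided by total presses).
#'
#' @param events a data frame of the trial's presses in order, with at least a
#'   `key` column; if `press_index` is present the rows are ordered by it
#'   (ties keep file order). All rows must belong to one participant, task
#'   and trial.
#' @param seq a [sequence_spec()].
#' @return A one-row data frame with columns `correct`, `wrong_key`,
#'   `wrong_order`, `total` and `error_rate` (`NA` when `total` is 0: the
#'   rate of an empty trial is undefined, not zero).
#' @examples
#' s <- sequence_spec(c("k1", "k2", "k3", "k4"))
#' score_trial(data.frame(key = rep(c("k1","k2","k3","k4"), 3)), s)
#' @export
score_trial <- function(events, seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  if (is.character(events)) events <- data.frame(key = events)
  if (!is.data.frame(events) || !"key" %in% names(events))
    stop("'events' must be a data frame with a 'key' column")
  for (col in c("participant", "task", "trial")) {
    if (col %in% names(events) && length(unique(events[[col]])) > 1L)
      stop("all events of a trial must share one ", col)
  }
  keys <- as.character(events$key)
  if ("press_index" %in% names(events))
    keys <- keys[order(events$press_index)]
  bad <- which(is.na(keys) | !nzchar(keys))
  if (length(bad))
    stop("unrepresentable key identifier at press ", bad[1],
         if ("press_index" %in% names(events))
           paste0(" (press_index ", events$press_index[order(events$press_index)][bad[1]], ")")
         else "")
  counts <- score_keys(keys, seq$keys)
  total <- sum(counts)
  data.frame(correct     = counts[["correct"]],
             wrong_key   = counts[["wrong_key"]],
             wrong_order = counts[["wrong_order"]],
             total       = total,
             error_rate  = if (total > 0)
               (counts[["wrong_key"]] + counts[["wrong_order"]]) / total else NA_real_)
}

#' Score a whole key-press log into a per-trial table
#'
#' Applies [score_trial()] to every observed participant x task x trial cell
#' of an event log. Trials that are absent from the log are reported (as an
#' attribute and a warning), never fabricated.
#'
#' @param events data frame with columns `participant`, `task`, `trial`,
#'   `press_index`, `key` (a `time_ms` column is accepted and ignored for
#'   scoring; presses with identical timestamps keep file order).
#' @param seqs a named list of [sequence_spec()] objects, one per task.
#' @param trials expected trial numbers per participant and task
#'   (default `1:20`); used only to report missing trials.
#' @return A data frame with one row per observed cell: `participant`,
#'   `task`, `trial`, `correct`, `wrong_key`, `wrong_order`, `total`,
#'   `error_rate`, ordered by participant, task, trial. Missing expected
#'   trials are listed in `attr(x, "missing_trials")`.
#' @export
score_dataset <- function(events, seqs, trials = 1:20) {
  need <- c("participant", "task", "trial", "press_index", "key")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.list(seqs) || is.null(names(seqs)))
    stop("'seqs' must be a named list of sequence specs, one per task")
  tasks <- unique(as.character(events$task))
  unk <- setdiff(tasks, names(seqs))
  if (length(unk)) stop("no sequence spec for task(s): ", paste(unk, collapse = ", "))
  dup <- duplicated(events[c("participant", "task", "trial", "press_index")])
  if (any(dup)) {
    d <- events[which(dup)[1], ]
    stop("duplicate press: participant ", d$participant, ", task ", d$task,
         ", trial ", d$trial, ", press_index ", d$press_index)
  }
  key_of <- interaction(events$participant, events$task, events$trial, drop = TRUE)
  groups <- split(seq_len(nrow(events)), key_of)
  rows <- lapply(groups, function(idx) {
    ev <- events[idx, , drop = FALSE]
    sc <- score_trial(ev, seqs[[as.character(ev$task[1])]])
    cbind(data.frame(participant = ev$participant[1], task = ev$task[1],
                     trial = ev$trial[1]), sc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$participant, out$task, out$trial), , drop = FALSE]
  rownames(out) <- NULL
  # report (participant, task) cells with absent expected trials
  missing_rows <- list()
  for (pt in split(out, interaction(out$participant, out$task, drop = TRUE))) {
    absent <- setdiff(trials, pt$trial)
    if (length(absent))
      missing_rows[[length(missing_rows) + 1L]] <-
        data.frame(participant = pt$participant[1], task = pt$task[1], trial = absent)
  }
  if (length(missing_rows)) {
    mt <- do.call(rbind, missing_rows)
    attr(out, "missing_trials") <- mt
    warning(nrow(mt), " expected trial(s) missing from the log (see attr 'missing_trials')")
  }
  out
}

#' Read a key-press event log
#'
#' @param file CSV with header `participant,task,trial,press_index,key,time_ms`.
#' @return data frame of events.
#' @export
read_events <- function(file) {
  ev <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("participant", "task", "trial", "press_index", "key")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop(file, " lacks column(s): ", paste(miss, collapse = ", "))
  ev
}

#' Write a per-trial score table
#' @param scores output of [score_dataset()].
#' @param file destination CSV path.
#' @export
write_trial_scores <- function(scores, file) {
  utils::write.csv(scores, file, row.names = FALSE, na = "")
  invisible(file)
}
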