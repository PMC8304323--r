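#' Construct a trial schedule
#'
#' A schedule is an ordered set of non-overlapping trials, each belonging to
#' one protocol segment (familiarization, training, buffer, evaluation) with
#' a condition flag (`S` = stressor present, `N` = normal) and, for training
#' trials, a success/error outcome. Task trials are at most 60 s; the buffer
#' consolidation block is exempt from that bound.
#'
#' @param trials Data frame with columns `segment`, `start`, `end`,
#'   `condition`, `outcome`.
#' @return A validated `trial_schedule` data frame with a `trial` id column.
#' @export
trial_schedule <- function(trials) {
  req <- c("segment", "start", "end", "condition", "outcome")
  if (!all(req %in% names(trials))) {
    stop_invalid("schedule", paste("missing column(s):",
                                   paste(setdiff(req, names(trials)), collapse = ", ")))
  }
  sch <- as.data.frame(trials)[, req]
  sch <- sch[order(sch$start), , drop = FALSE]
  sch <- cbind(trial = seq_len(nrow(sch)), sch)
  rownames(sch) <- NULL
  class(sch) <- c("trial_schedule", "data.frame")
  validate_schedule(sch)
}

validate_schedule <- function(sch) {
  segs <- c("familiarization", "training", "buffer", "evaluation")
  if (!all(sch$segment %in% segs)) {
    stop_invalid("schedule", "unknown segment label")
  }
  if (!all(sch$condition %in% c("S", "N"))) {
    stop_invalid("schedule", "condition must be 'S' or 'N'")
  }
  if (!all(sch$outcome %in% c("success", "error", "n/a"))) {
    stop_invalid("schedule", "outcome must be success/error/n/a")
  }
  dur <- sch$end - sch$start
  if (any(dur <= 0)) stop_invalid("schedule", "trials must have positive duration")
  task <- sch$segment != "buffer"
  if (any(dur[task] > 60 + 1e-9)) {
    stop_invalid("schedule", "task trials must be at most 60 s")
  }
  if (nrow(sch) > 1L && any(sch$start[-1L] < sch$end[-nrow(sch)] - 1e-9)) {
    stop_invalid("schedule", "trials must not overlap")
  }
  ev <- sch$condition[sch$segment == "evaluation"]
  if (length(ev) && length(ev) %% 2L == 0L && sum(ev == "S") != length(ev) / 2L) {
    stop_invalid("schedule", "evaluation trials must be half S and half N")
  }
  sch
}

#' Build a protocol-faithful trial schedule
#'
#' Generates one participant's session: 3 familiarization trials, 8 training
#' trials (each independently flagged as an error with probability
#' `training_error_prob`; an errored trial is followed by an inserted
#' familiarization trial), a consolidation buffer block, and 8 evaluation
#' trials of which exactly 4 are under stressors (S) and 4 under normal
#' conditions (N) in counterbalanced (seeded, balanced) order. For the stress
#' group, familiarization/training trials carry condition S (with probability
#' `stress_exposure_fraction` each); for the control group they are N.
#'
#' @param config A [synthetic_config()].
#' @param group `"stress"` or `"control"`.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A `trial_schedule`.
#' @export
build_protocol_schedule <- function(config = synthetic_config(),
                                    group = c("stress", "control"),
                                    seed = 1L) {
  group <- match.arg(group)
  with_seed(seed, {
    draw_dur <- function() stats::runif(1, config$trial_min_s, config$trial_max_s)
    base_cond <- function() {
      if (group == "stress" &&
          stats::runif(1) <= config$stress_exposure_fraction) "S" else "N"
    }
    rows <- list()
    t0 <- 0
    push <- function(segment, dur, condition, outcome) {
      rows[[length(rows) + 1L]] <<- data.frame(
        segment = segment, start = t0, end = t0 + dur,
        condition = condition, outcome = outcome)
      t0 <<- t0 + dur + config$gap_s
    }
    for (i in 1:3) push("familiarization", draw_dur(), base_cond(), "n/a")
    for (i in 1:8) {
      err <- stats::runif(1) < config$training_error_prob
      push("training", draw_dur(), base_cond(), if (err) "error" else "success")
      if (err) push("familiarization", draw_dur(), base_cond(), "n/a")
    }
    push("buffer", config$buffer_s, "N", "n/a")
    ev_cond <- sample(rep(c("S", "N"), each = 4L))
    for (i in 1:8) push("evaluation", draw_dur(), ev_cond[i], "n/a")
    trial_schedule(do.call(rbind, rows))
  })
}

#' Label trials for classification
#'
#' Applies the labeling rule used to build the feature table:
#' familiarization trials and errored training trials are `encoding`
#' (an inserted familiarization trial after an error is itself a
#' familiarization trial, hence encoding); evaluation trials are `retrieval`;
#' successful training trials and the buffer are unlabeled (`NA`) and never
#' enter the dataset.
#'
#' @param schedule A `trial_schedule`.
#' @return Character vector, one entry per trial: "encoding", "retrieval" or NA.
#' @export
trial_labels <- function(schedule) {
  lab <- rep(NA_character_, nrow(schedule))
  lab[schedule$segment == "familiarization"] <- "encoding"
  lab[schedule$segment == "training" & schedule$outcome == "error"] <- "encoding"
  lab[schedule$segment == "evaluation"] <- "retrieval"
  lab
}

#' Write / read a trial schedule as CSV
#'
#' @param schedule A `trial_schedule`.
#' @param path Output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_schedule(df[, c("segment", "start", "end", "condition", "outcome")])
}
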