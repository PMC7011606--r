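#' Read and write interaction episode logs
#'
#' Episode CSV schema (header mandatory): `timestamp_s` (seconds, strictly
#' increasing), `robot_action` in `f/s/b`, `child_state` in `NL/L/TA/M`
#' (`TA` serializes the touching/aroused state). The session duration is
#' carried in a `# duration_s:` comment line when it exceeds the last
#' timestamp.
#'
#' @param path File path.
#' @return [read_episode()]: a [episode()].
#' @export
read_episode <- function(path) {
  lines <- readLines(path)
  dur <- NA_real_
  meta <- grep("^#", lines)
  for (m in meta) {
    if (grepl("duration_s:", lines[m])) {
      dur <- as.numeric(sub(".*duration_s:\\s*", "", lines[m]))
    }
  }
  if (length(meta)) lines <- lines[-meta]
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "robot_action", "child_state")
  if (!all(need %in% names(df))) {
    stop("episode file ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad_state <- which(!df$child_state %in% cri_states())
  if (length(bad_state)) {
    stop("episode file ", path, ": unknown child_state '",
         df$child_state[bad_state[1L]], "' at data row ", bad_state[1L],
         call. = FALSE)
  }
  bad_act <- which(!df$robot_action %in% cri_actions())
  if (length(bad_act)) {
    stop("episode file ", path, ": unknown robot_action '",
         df$robot_action[bad_act[1L]], "' at data row ", bad_act[1L],
         call. = FALSE)
  }
  episode(df$timestamp_s, df$robot_action, df$child_state,
          duration = if (is.finite(dur)) dur else NULL)
}

#' @param ep A [episode()].
#' @rdname read_episode
#' @export
write_episode <- function(ep, path) {
  stopifnot(inherits(ep, "cri_episode"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s: %.10g", episode_duration(ep)), con)
  utils::write.csv(as.data.frame(unclass(ep))[
    c("timestamp_s", "robot_action", "child_state")], con, row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Read and write per-frame annotation tables
#'
#' Annotation CSV schema: `frame` (0-based, strictly increasing), `label`
#' (action class or empty for unlabeled frames), `visible_view_0` ..
#' `visible_view_{V-1}` (logical child-visibility flags), optional `event`
#' (`look`, `move_toward`, `ascend_complete`, or empty).
#'
#' @param path File path.
#' @param fps Frames per second recorded with the table (default 15).
#' @return A data frame of class `annotation_table` with attribute `fps`.
#' @export
read_annotations <- function(path, fps = 15) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_table(df, fps = fps)
}

#' @param df Data frame with the schema above.
#' @rdname read_annotations
#' @export
annotation_table <- function(df, fps = 15) {
  if (!"frame" %in% names(df)) stop("annotation table needs a 'frame' column",
                                    call. = FALSE)
  if (nrow(df) && any(diff(df$frame) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  df$label[df$label %in% c("", "none")] <- NA_character_
  bad <- which(!is.na(df$label) & !df$label %in% action_classes())
  if (length(bad)) {
    stop("unknown action label '", df$label[bad[1L]], "' at data row ",
         bad[1L], call. = FALSE)
  }
  if ("event" %in% names(df)) {
    df$event[df$event %in% ""] <- NA_character_
    bad_ev <- which(!is.na(df$event) &
                      !df$event %in% c("look", "move_toward",
                                       "ascend_complete"))
    if (length(bad_ev)) {
      stop("unknown event '", df$event[bad_ev[1L]], "' at data row ",
           bad_ev[1L], call. = FALSE)
    }
  }
  attr(df, "fps") <- fps
  class(df) <- unique(c("annotation_table", class(df)))
  df
}

#' @param ann An `annotation_table`.
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  out <- as.data.frame(unclass(ann))
  out$label[is.na(out$label)] <- ""
  if ("event" %in% names(out)) out$event[is.na(out$event)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment per-frame annotations into action instances
#'
#' Maximal runs of identical labels become instances with half-open 0-based
#' frame intervals `[start, end)`; unlabeled frames (and gaps in the frame
#' index) break runs. This mirrors the preprocessing in which per-frame
#' labels determine the temporal boundaries of every action instance.
#'
#' @param annotations An `annotation_table`.
#' @return Data frame with columns `label`, `start_frame`, `end_frame`
#'   (half-open), empty when no frame is labeled.
#' @export
segment_instances <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (nrow(annotations) == 0L) {
    return(data.frame(label = character(0), start_frame = integer(0),
                      end_frame = integer(0)))
  }
  fr <- annotations$frame
  lb <- annotations$label
  out <- list()
  run_lab <- NA_character_
  run_start <- NA_integer_
  prev_fr <- NA_integer_
  flush <- function(end_frame) {
    if (!is.na(run_lab)) {
      out[[length(out) + 1L]] <<- data.frame(
        label = run_lab, start_frame = run_start, end_frame = end_frame)
    }
  }
  for (i in seq_along(fr)) {
    contiguous <- !is.na(prev_fr) && fr[i] == prev_fr + 1L
    same <- !is.na(lb[i]) && !is.na(run_lab) && lb[i] == run_lab &&
      contiguous
    if (!same) {
      flush(if (is.na(prev_fr)) NA_integer_ else prev_fr + 1L)
      run_lab <- lb[i]
      run_start <- fr[i]
    }
    prev_fr <- fr[i]
  }
  flush(prev_fr + 1L)
  if (!length(out)) {
    return(data.frame(label = character(0), start_frame = integer(0),
                      end_frame = integer(0)))
  }
  do.call(rbind, out)
}

#' Session-level interaction indicators
#'
#' Computes the annotation-derived indicators of child-robot interaction for
#' one trial: the number of times per minute the child looked at the robot,
#' the number of times per minute it moved towards or followed the robot, and
#' the raw count of completed ascents. Events are annotation rows, as they
#' were scored by human annotators from the recordings.
#'
#' @param annotations An `annotation_table` with an `event` column.
#' @param trial_duration_s Trial length in seconds (the free-play trial of the
#'   protocol lasts 3 minutes, i.e. 180 s).
#' @return List with `looks_per_min`, `moves_per_min`, `ascents`.
#' @export
session_metrics <- function(annotations, trial_duration_s) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (!is.finite(trial_duration_s) || trial_duration_s <= 0) {
    stop("trial_duration_s must be positive", call. = FALSE)
  }
  ev <- if ("event" %in% names(annotations)) annotations$event else {
    rep(NA_character_, nrow(annotations))
  }
  mins <- trial_duration_s / 60
  list(looks_per_min = sum(ev == "look", na.rm = TRUE) / mins,
       moves_per_min = sum(ev == "move_toward", na.rm = TRUE) / mins,
       ascents = sum(ev == "ascend_complete", na.rm = TRUE))
}

#' Read and write embedding feature tables
#'
#' The on-disk form is a plain CSV feature table (`instance_id`, `view_id`,
#' `label`, then feature columns `f1..fD`) plus a sidecar JSON manifest
#' recording the embedding dimension, view range and provenance (seed,
#' resolved parameters) of the run that produced it.
#'
#' @param bags List of [mv_instance()] bags.
#' @param path CSV path; the manifest is written to `paste0(path, ".json")`.
#' @param manifest Optional named list merged into the manifest.
#' @export
write_feature_bags <- function(bags, path, manifest = list()) {
  u <- unroll_bags(bags)
  ids <- vapply(bags, function(b) as.character(b$instance_id), character(1L))
  view_ids <- unlist(lapply(bags, function(b) b$view_ids))
  d <- ncol(u$x)
  df <- data.frame(instance_id = ids[u$bag], view_id = view_ids,
                   label = u$label, stringsAsFactors = FALSE)
  feat <- as.data.frame(u$x)
  names(feat) <- paste0("f", seq_len(d))
  utils::write.csv(cbind(df, feat), path, row.names = FALSE, quote = FALSE)
  man <- utils::modifyList(list(n_instances = length(bags),
                                n_views_total = nrow(u$x), dim = d,
                                view_id_range = range(view_ids),
                                classes = action_classes()), manifest)
  jsonlite::write_json(man, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @param max_view_id Largest legal `view_id` (default 4, a five-camera rig).
#' @rdname write_feature_bags
#' @export
read_feature_bags <- function(path, max_view_id = 4L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "view_id", "label")
  if (!all(need %in% names(df))) {
    stop("feature table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$view_id < 0L | df$view_id > max_view_id)) {
    bad <- which(df$view_id < 0L | df$view_id > max_view_id)[1L]
    stop("view_id ", df$view_id[bad], " at data row ", bad,
         " outside 0..", max_view_id, call. = FALSE)
  }
  feat_cols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!length(feat_cols)) stop("no feature columns f1..fD found",
                               call. = FALSE)
  lapply(split(seq_len(nrow(df)), df$instance_id)[
    unique(df$instance_id)], function(rows) {
      lab <- unique(df$label[rows])
      if (length(lab) != 1L) {
        stop("instance ", df$instance_id[rows[1L]],
             " carries conflicting labels", call. = FALSE)
      }
      mv_instance(df$instance_id[rows[1L]],
                  as.matrix(df[rows, feat_cols, drop = FALSE]),
                  view_ids = df$view_id[rows],
                  label = if (is.na(lab) || lab == "") NA_character_ else lab)
    })
}

#' Read and write a fitted MDP model file
#'
#' JSON container for everything needed to reproduce planning: states,
#' actions, the count tensor, the estimator and its settings, utilities, and
#' (optionally) a policy.
#'
#' @param counts A [transition_counts()] tensor.
#' @param estimator `"ml"` or `"smoothed"`.
#' @param lambda Smoothing pseudo-count.
#' @param gamma Discount recorded for planning.
#' @param utility Per-state utility vector.
#' @param policy Optional [cri_policy()].
#' @param path Output path.
#' @export
write_mdp_model <- function(counts, path, estimator = "smoothed", lambda = 1,
                            gamma = 0.95, utility = cri_utility(),
                            policy = NULL) {
  obj <- list(states = cri_states(), actions = cri_actions(),
              counts = as.vector(counts), dim = dim(counts),
              estimator = estimator, lambda = lambda, gamma = gamma,
              utility = as.numeric(utility))
  if (!is.null(policy)) {
    obj$policy <- as.list(stats::setNames(unname(policy[cri_states()]),
                                          cri_states()))
    obj$policy_provenance <- attr(policy, "provenance")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mdp_model
#' @export
read_mdp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$states), cri_states())) {
    stop("model file states differ from ", paste(cri_states(),
                                                 collapse = ","),
         call. = FALSE)
  }
  counts <- transition_counts()
  counts[] <- as.integer(obj$counts)
  out <- list(counts = counts, estimator = obj$estimator,
              lambda = obj$lambda, gamma = obj$gamma,
              utility = stats::setNames(as.numeric(obj$utility),
                                        cri_states()))
  if (!is.null(obj$policy)) {
    out$policy <- cri_policy(unlist(obj$policy),
                             provenance = obj$policy_provenance %||% "custom")
  }
  out
}
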