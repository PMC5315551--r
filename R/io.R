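#' Write sessions to a trial-table CSV
#'
#' One row per trial with columns subject, condition, block, index,
#' trial_type, ssd_ms, responded, rt_ms, stop_success and the generator
#' ground-truth go_finish_ms. Times are ms throughout.
#'
#' @param sessions a single `sst_session`, a list of them, or an already
#'   assembled trial-table data.frame.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_trials <- function(sessions, path) {
  df <- sessions_to_table(sessions)
  data.table::fwrite(df, path)
  invisible(df)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  needed <- c("subject", "condition", "block", "index", "trial_type",
              "ssd_ms", "responded", "rt_ms", "stop_success")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname write_trials
#' @export
sessions_to_table <- function(sessions) {
  if (is.data.frame(sessions)) return(sessions)
  if (inherits(sessions, "sst_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s)
    cbind(subject = s$subject_id, condition = s$condition, s$trials,
          stringsAsFactors = FALSE)))
}

#' Write / read an epochs container
#'
#' Plain-text container: `<stem>.json` holds the metadata (sampling rate,
#' times, alignment, labels and the per-epoch trial table) and
#' `<stem>.csv` the amplitudes, one row per (trial, channel) with one
#' column per sample. Round-trips an [eeg_epochs()] object.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param stem path without extension.
#' @return `write_epochs` the stem, invisibly; `read_epochs` the restored
#'   [eeg_epochs()].
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(srate = epochs$srate, times = epochs$times,
               alignment = epochs$alignment, labels = epochs$labels,
               trials = epochs$trials, units = "microvolt, ms")
  jsonlite::write_json(meta, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  dt <- data.table::data.table(trial = rep(seq_len(d[1]), each = d[2]),
                               channel = rep(epochs$labels, d[1]))
  dt <- cbind(dt, data.table::as.data.table(flat))
  data.table::fwrite(dt, paste0(stem, ".csv"))
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(paste0(stem, ".csv"))
  n_trial <- max(dt$trial)
  labels <- meta$labels
  n_ch <- length(labels)
  n_samp <- ncol(dt) - 2L
  flat <- as.matrix(dt[, -(1:2)])
  data <- aperm(array(t(flat), c(n_samp, n_ch, n_trial)), c(3, 2, 1))
  trials <- as.data.frame(meta$trials, stringsAsFactors = FALSE)
  eeg_epochs(data, as.numeric(meta$srate), as.numeric(meta$times),
             meta$alignment, labels, trials)
}

#' Export an ERP as a channels x samples CSV
#'
#' First column is the channel label; remaining columns are the sample
#' times in ms.
#'
#' @param erp an [new_erp()] object.
#' @param path output CSV path.
#' @export
write_erp_csv <- function(erp, path) {
  df <- data.frame(channel = erp$labels, erp$data, check.names = FALSE)
  names(df)[-1] <- as.character(erp$times)
  data.table::fwrite(df, path)
  invisible(df)
}

#' Serialize the model space to YAML
#'
#' Nodes with MNI coordinates, typed edges, the nine modulation masks and
#' the family partition, in one canonical document that tests pin.
#'
#' @param space a [build_model_space()].
#' @param path output YAML path; when NULL the YAML text is returned.
#' @export
model_space_to_yaml <- function(space, path = NULL) {
  obj <- list(
    nodes = lapply(seq_len(nrow(space$nodes)), function(i)
      list(name = space$nodes$name[i],
           mni = if (space$nodes$hidden[i]) NULL else
             c(space$nodes$x[i], space$nodes$y[i], space$nodes$z[i]),
           hidden = space$nodes$hidden[i])),
    input_nodes = space$input_nodes,
    edges = lapply(seq_len(nrow(space$edges)), function(i)
      list(from = space$edges$from[i], to = space$edges$to[i],
           type = space$edges$type[i], directed = space$edges$directed[i])),
    models = space$models,
    families = space$families)
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [run_config()] object.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  obj <- lapply(cfg, unclass)
  obj$task$proportions <- as.list(obj$task$proportions)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    raw[setdiff(names(raw), c("task", "params", "on_effects"))],
    list(task = do.call(task_config,
                        c(raw$task[setdiff(names(raw$task), "proportions")],
                          list(proportions = unlist(raw$task$proportions)))),
         params = do.call(race_params, raw$params),
         on_effects = raw$on_effects)))
}
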