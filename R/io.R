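# Plain-text persistence: session bundles and agent checkpoints are
# written as directories of CSV tables plus a JSON metadata file, episode
# logs and maps as flat CSV.

#' Write / read a session bundle
#'
#' The bundle is stored as a directory: \code{trajectories.csv} (all
#' trials, with a \code{trial} column), \code{activity.csv},
#' \code{units.csv} and \code{meta.json}.
#'
#' @param bundle a \code{\link{generate_session}} result.
#' @param dir target directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trs <- bundle$trajectories
  df <- do.call(rbind, Map(function(tr, i) cbind(trial = i, tr),
                           trs, seq_along(trs)))
  utils::write.csv(df, file.path(dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$activity),
                   file.path(dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(bundle$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(task = bundle$task, stage = bundle$stage, seed = bundle$seed,
         frame_times = bundle$frame_times,
         trial_frames = as.data.frame(bundle$trial_frames),
         policy = unclass(bundle$policy)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session_bundle
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "trajectories.csv"))
  trs <- lapply(split(df, df$trial), function(d) {
    rownames(d) <- NULL
    d[, setdiff(names(d), "trial")]
  })
  names(trs) <- NULL
  act <- as.matrix(utils::read.csv(file.path(dir, "activity.csv")))
  dimnames(act) <- NULL
  units <- utils::read.csv(file.path(dir, "units.csv"),
                           stringsAsFactors = FALSE)
  pol <- meta$policy
  policy <- structure(pol, class = "policy_spec")
  structure(list(task = meta$task, stage = meta$stage, trajectories = trs,
                 activity = act, frame_times = meta$frame_times,
                 trial_frames = as.matrix(meta$trial_frames),
                 units = units, policy = policy, seed = meta$seed),
            class = "session_bundle")
}

#' Write episode logs to CSV
#'
#' @param trajectories a \code{"trajectory_set"} (or list of episode
#'   data.frames).
#' @param file output CSV path; episodes are stacked with an
#'   \code{episode} column.
#' @return \code{file}, invisibly.
#' @export
write_episode_logs <- function(trajectories, file) {
  eps <- as_traj_list(trajectories)
  df <- do.call(rbind, Map(function(tr, i) cbind(episode = i, tr),
                           eps, seq_along(eps)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

pack_net <- function(net) {
  list(sizes = net$sizes,
       W = lapply(net$W, function(w) list(dim = dim(w), x = as.numeric(w))),
       b = net$b,
       mask = net$mask)
}

unpack_net <- function(pk) {
  list(W = lapply(pk$W, function(w) matrix(w$x, w$dim[1], w$dim[2])),
       b = lapply(pk$b, as.numeric),
       sizes = as.numeric(pk$sizes),
       mask = if (is.null(pk$mask)) NULL else lapply(pk$mask, as.numeric))
}

pack_critic <- function(cr) {
  list(kind = cr$kind, op = cr$op,
       nets = lapply(critic_nets(cr), pack_net))
}

unpack_critic <- function(pk) {
  nets <- lapply(pk$nets, unpack_net)
  if (pk$kind == "single") critic_single(nets[[1]])
  else critic_composite(nets[[1]], nets[[2]], pk$op)
}

#' Save / load an agent checkpoint
#'
#' All network parameters (actor, twin critics and their targets, ablation
#' masks) are written as full-precision JSON together with the training
#' configuration, composition metadata and learning curve.
#'
#' @param agent a \code{"sac_agent"}.
#' @param file output path (.json).
#' @return \code{file} (or the restored agent for \code{load_agent}).
#' @export
save_agent <- function(agent, file) {
  stopifnot(inherits(agent, "sac_agent"))
  pk <- list(actor = pack_net(agent$actor),
             critics = lapply(agent$critics, pack_critic),
             targets = lapply(agent$targets, pack_critic),
             config = unclass(agent$config),
             composition = agent$composition,
             ablation = agent$ablation,
             epoch_returns = agent$epoch_returns,
             epoch_disc_returns = agent$epoch_disc_returns)
  jsonlite::write_json(pk, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname save_agent
#' @export
load_agent <- function(file) {
  pk <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyMatrix = FALSE,
                            simplifyDataFrame = FALSE)
  cfg <- pk$config
  cfg$hidden <- as.integer(unlist(cfg$hidden))
  config <- do.call(sac_config, cfg[setdiff(names(cfg), character(0))])
  structure(list(actor = unpack_net(pk$actor),
                 critics = lapply(pk$critics, unpack_critic),
                 targets = lapply(pk$targets, unpack_critic),
                 config = config,
                 env_config = NULL,
                 composition = pk$composition,
                 ablation = pk$ablation,
                 epoch_returns = as.numeric(unlist(pk$epoch_returns)),
                 epoch_disc_returns = as.numeric(unlist(pk$epoch_disc_returns))),
            class = "sac_agent")
}

#' Export a binned map as CSV
#'
#' @param map a \code{value_map}, \code{q_map}, or plain vector/matrix on
#'   an arena binning.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_map_csv <- function(map, file) {
  M <- if (inherits(map, "value_map")) data.frame(bin = seq_along(map$v), v = map$v)
       else if (inherits(map, "q_map")) data.frame(bin = seq_len(nrow(map$q)), map$q)
       else as.data.frame(map)
  utils::write.csv(M, file, row.names = FALSE)
  invisible(file)
}
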