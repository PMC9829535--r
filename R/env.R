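#' Arena task configuration
#'
#' Builds a validated configuration for the continuous object-manipulation
#' arena.  The arena spans \code{[-1, 1]^2} (2.0 x 2.0 arbitrary units).
#' Three task rules are available:
#' \describe{
#'   \item{task1}{the agent must move into a 0.8 x 0.8 reward zone centered
#'     at the origin; reaching the zone ends the episode with a reward.}
#'   \item{task2}{the agent is stationary (movement is inert) and obtains a
#'     reward by emitting a lick whose magnitude exceeds the lick threshold.}
#'   \item{composite}{the agent must first reach a small target rectangle
#'     (0.1 wide, 0.0031 tall, centered in x at the bottom edge), after which
#'     movement is frozen, and then lick to obtain the reward.}
#' }
#'
#' @param task one of \code{"task1"}, \code{"task2"}, \code{"composite"}.
#' @param arena_halfwidth half-width of the square arena in a.u.
#' @param lick_threshold lick magnitude above which a lick event is counted.
#' @param max_episode_steps episode cap; reaching it truncates with reward 0.
#' @param reward_value reward delivered on task success.
#' @param fixed_start optional \code{c(x, y)} start used for every reset
#'   (task1/composite variants with a deterministic initial condition).
#' @param identical_reward_zone if \code{TRUE} (composite only), the target
#'   is replaced by the task1 reward zone, making the two zones identical.
#' @param control_init_task2 if \code{TRUE} (task2 only), the agent sits at
#'   the top-middle of the arena instead of the bottom-middle; used for
#'   control initialization so that the mean composite Q stays comparable.
#' @param altered_reward optional list \code{list(axis, high_side, high, low)}
#'   splitting the task1 reward zone into a high- and a low-reward side
#'   (\code{axis} is \code{"x"} or \code{"y"}; \code{high_side} is
#'   \code{"positive"} or \code{"negative"}).
#'
#' @return an object of class \code{"env_config"}.
#' @export
env_config <- function(task = c("task1", "task2", "composite"),
                       arena_halfwidth = 1.0,
                       lick_threshold = 0.08,
                       max_episode_steps = 300L,
                       reward_value = 1.0,
                       fixed_start = NULL,
                       identical_reward_zone = FALSE,
                       control_init_task2 = FALSE,
                       altered_reward = NULL) {
  task <- match.arg(task)
  stopifnot(arena_halfwidth > 0, max_episode_steps > 0)
  if (!(lick_threshold > 0 && lick_threshold < 0.1)) {
    stop("lick_threshold must lie in (0, 0.1)")
  }
  a <- arena_halfwidth
  # reward zone / target rectangles as c(xmin, xmax, ymin, ymax)
  reward_zone <- c(-0.4, 0.4, -0.4, 0.4)
  target_region <- c(-0.05, 0.05, -a, -a + 0.0031)
  if (identical_reward_zone) {
    if (task != "composite") stop("identical_reward_zone applies to the composite task only")
    target_region <- reward_zone
  }
  for (rect in list(reward_zone, target_region)) {
    if (rect[1] < -a || rect[2] > a || rect[3] < -a || rect[4] > a ||
        rect[1] >= rect[2] || rect[3] >= rect[4]) {
      stop("zone geometry must be a proper rectangle inside the arena")
    }
  }
  if (!is.null(fixed_start)) {
    fixed_start <- as.numeric(fixed_start)
    if (length(fixed_start) != 2 || any(abs(fixed_start) > a)) {
      stop("fixed_start must be a length-2 position inside the arena")
    }
  }
  if (control_init_task2 && task != "task2") {
    stop("control_init_task2 applies to task2 only")
  }
  # task2: licking is rewarded only within reach of the water spout, a
  # small region around the agent's start position (bottom middle, or top
  # middle under control initialization)
  spout_region <- NULL
  if (task == "task2") {
    y0 <- if (control_init_task2) 0.98 * a else -0.98 * a
    spout_region <- c(-0.1, 0.1, max(y0 - 0.1, -a), min(y0 + 0.1, a))
  }
  if (!is.null(altered_reward)) {
    if (task != "task1") stop("altered_reward applies to task1 only")
    stopifnot(is.list(altered_reward),
              altered_reward$axis %in% c("x", "y"),
              altered_reward$high_side %in% c("positive", "negative"))
    if (is.null(altered_reward$high)) altered_reward$high <- 1.0
    if (is.null(altered_reward$low)) altered_reward$low <- 0.1
  }
  structure(list(task = task,
                 arena_halfwidth = a,
                 reward_zone = reward_zone,
                 target_region = target_region,
                 lick_threshold = lick_threshold,
                 max_episode_steps = as.integer(max_episode_steps),
                 reward_value = reward_value,
                 fixed_start = fixed_start,
                 identical_reward_zone = identical_reward_zone,
                 control_init_task2 = control_init_task2,
                 spout_region = spout_region,
                 altered_reward = altered_reward),
            class = "env_config")
}

in_rect <- function(x, y, rect) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

# goal rectangle of a task: the zone whose entry matters for termination
goal_rect <- function(config) {
  if (config$task == "task1") config$reward_zone else config$target_region
}

#' Create an arena environment
#'
#' Instantiates a simulator handle with its own deterministic random stream.
#' The state exposed to an agent is \code{(x, y, vx, vy)} where the velocity
#' components are the last applied movement.
#'
#' @param config an \code{\link{env_config}}.
#' @param seed integer seed for the environment's private random stream
#'   (initial positions).
#' @return an object of class \code{"arena_env"} (an R environment) exposing
#'   \code{\link{env_reset}} and \code{\link{env_step}}.
#' @export
make_env <- function(config, seed = 0L) {
  stopifnot(inherits(config, "env_config"))
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$rng <- make_rng(seed)
  e$state <- NULL
  e$done <- TRUE
  class(e) <- "arena_env"
  e
}

# private RNG stream: save/restore .Random.seed so env randomness is
# reproducible and isolated from the caller's stream
make_rng <- function(seed) {
  old <- get_global_seed()
  set.seed(seed)
  st <- .Random.seed
  restore_global_seed(old)
  new_stream(st)
}

new_stream <- function(state) {
  s <- new.env(parent = emptyenv())
  s$state <- state
  s
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_stream <- function(stream, expr) {
  old <- get_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(old)
  })
  expr
}

#' Reset an arena environment
#'
#' task1/composite: the agent starts at a uniform random position outside the
#' goal rectangle (or exactly at \code{fixed_start} when configured).
#' task2 starts at the bottom-middle \code{(0, -0.98)} (top-middle
#' \code{(0, 0.98)} under control initialization).  Velocity is zero and the
#' frozen flag cleared.
#'
#' @param env an \code{"arena_env"}.
#' @return the initial state: \code{list(position, velocity, frozen, step_index)}.
#' @export
env_reset <- function(env) {
  cfg <- env$config
  a <- cfg$arena_halfwidth
  if (cfg$task == "task2") {
    pos <- if (cfg$control_init_task2) c(0, 0.98 * a) else c(0, -0.98 * a)
  } else if (!is.null(cfg$fixed_start)) {
    pos <- cfg$fixed_start
  } else {
    rect <- goal_rect(cfg)
    pos <- with_stream(env$rng, {
      repeat {
        p <- stats::runif(2, -a, a)
        if (!in_rect(p[1], p[2], rect)) break
      }
      p
    })
  }
  env$state <- list(position = pos, velocity = c(0, 0),
                    frozen = FALSE, step_index = 0L)
  env$done <- FALSE
  env$state
}

#' Advance an arena environment by one action
#'
#' Movement components are clipped to \code{[-0.1, 0.1]} and the lick
#' component to \code{[0, 0.1]}; a lick event is counted when the lick
#' magnitude exceeds the configured threshold.  Movement is inert after
#' the composite target has been reached (frozen); in task2 movement is
#' free but irrelevant to the reward, so the agent's experience stays
#' concentrated around its bottom-middle start.  A movement component
#' that would cross an arena wall is rejected (the position stays put in
#' that coordinate; there is no sliding along walls), so positions never
#' leave the arena and the composite target is entered only by landing
#' inside it.
#'
#' @param env an \code{"arena_env"} that has been reset.
#' @param action numeric \code{c(dx, dy, lick)} (lick may be omitted, taken
#'   as 0).
#' @return \code{list(state, reward, done, info)} where \code{info} carries
#'   flags \code{lick_event}, \code{entered_zone}, \code{truncated}.
#' @export
env_step <- function(env, action) {
  if (env$done) stop("env_step() called on a finished episode; call env_reset()")
  cfg <- env$config
  a <- cfg$arena_halfwidth
  action <- as.numeric(action)
  if (length(action) == 2) action <- c(action, 0)
  move <- pmin(pmax(action[1:2], -0.1), 0.1)
  lick <- min(max(action[3], 0), 0.1)
  lick_event <- lick > cfg$lick_threshold

  st <- env$state
  was_frozen <- st$frozen
  movable <- !was_frozen
  if (movable) {
    # a movement component that would leave the arena is rejected (the
    # wall blocks it; there is no sliding along or sticking to walls)
    cand <- st$position + move
    newpos <- ifelse(abs(cand) <= a, cand, st$position)
    applied <- newpos - st$position
  } else {
    newpos <- st$position
    applied <- c(0, 0)
  }

  reward <- 0
  done <- FALSE
  entered <- FALSE
  if (cfg$task == "task1") {
    if (in_rect(newpos[1], newpos[2], cfg$reward_zone)) {
      entered <- TRUE
      done <- TRUE
      reward <- task1_reward(cfg, newpos)
    }
  } else if (cfg$task == "task2") {
    if (lick_event && in_rect(newpos[1], newpos[2], cfg$spout_region)) {
      reward <- cfg$reward_value
      done <- TRUE
    }
  } else { # composite
    frozen <- was_frozen
    if (!frozen && in_rect(newpos[1], newpos[2], cfg$target_region)) {
      frozen <- TRUE
      entered <- TRUE
    }
    # reward requires the target to have been entered at a strictly
    # earlier step and a lick event now
    if (was_frozen && lick_event) {
      reward <- cfg$reward_value
      done <- TRUE
    }
    st$frozen <- frozen
  }

  step_index <- st$step_index + 1L
  truncated <- FALSE
  if (!done && step_index >= cfg$max_episode_steps) {
    done <- TRUE
    truncated <- TRUE
  }

  env$state <- list(position = newpos, velocity = applied,
                    frozen = isTRUE(st$frozen), step_index = step_index)
  env$done <- done
  list(state = env$state, reward = reward, done = done,
       info = list(lick_event = lick_event, entered_zone = entered,
                   truncated = truncated))
}

task1_reward <- function(cfg, pos) {
  ar <- cfg$altered_reward
  if (is.null(ar)) return(cfg$reward_value)
  coord <- if (ar$axis == "x") pos[1] else pos[2]
  on_high <- if (ar$high_side == "positive") coord >= 0 else coord < 0
  if (on_high) ar$high else ar$low
}

#' Run one episode under a policy function
#'
#' @param env an \code{"arena_env"}.
#' @param policy function mapping the state vector \code{c(x, y, vx, vy)} to
#'   an action \code{c(dx, dy, lick)}.
#' @param record if \code{TRUE}, return a step-by-step log.
#' @return a \code{data.frame} with columns
#'   \code{t, x, y, dx, dy, lick, reward, done} (positions are those at the
#'   start of each step; \code{dx, dy, lick} the action taken).
#' @export
run_episode <- function(env, policy, record = TRUE) {
  st <- env_reset(env)
  n <- env$config$max_episode_steps
  out <- matrix(NA_real_, n, 8)
  k <- 0L
  repeat {
    sv <- c(st$position, st$velocity)
    act <- policy(sv)
    res <- env_step(env, act)
    k <- k + 1L
    if (record) {
      out[k, ] <- c(k, st$position[1], st$position[2],
                    act[1], act[2], if (length(act) >= 3) act[3] else 0,
                    res$reward, as.numeric(res$done))
    }
    st <- res$state
    if (res$done) break
  }
  if (!record) return(invisible(NULL))
  out <- out[seq_len(k), , drop = FALSE]
  colnames(out) <- c("t", "x", "y", "dx", "dy", "lick", "reward", "done")
  as.data.frame(out)
}

#' @export
print.env_config <- function(x, ...) {
  cat("Arena task configuration:", x$task, "\n")
  cat(sprintf("  arena: [%.1f, %.1f]^2 a.u.\n", -x$arena_halfwidth, x$arena_halfwidth))
  rect <- goal_rect(x)
  cat(sprintf("  goal rectangle: x in [%.4g, %.4g], y in [%.4g, %.4g]\n",
              rect[1], rect[2], rect[3], rect[4]))
  cat(sprintf("  lick threshold: %.2f; max episode steps: %d; reward: %g\n",
              x$lick_threshold, x$max_episode_steps, x$reward_value))
  invisible(x)
}
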