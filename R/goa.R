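#' Configuration for the Grasshopper Optimization Algorithm
#'
#' The GOA is a swarm metaheuristic in which candidate solutions attract or
#' repel one another through a distance-dependent social force
#' `s(r) = f * exp(-r / l) - exp(-r)` while a comfort-zone coefficient `c`
#' decays linearly from `c_max` to `c_min`, shifting the swarm from global
#' exploration to local exploitation around the incumbent best.
#'
#' @param bounds Data frame with one row per dimension and columns `lo`, `hi`
#'   and `kind` (`"continuous"`, `"integer"` or `"log"`); `log` dimensions are
#'   searched in log10 space, `integer` dimensions are rounded to the nearest
#'   integer after every update.
#' @param n_pop Swarm size N (>= 2, default 30).
#' @param iterations Number of iterations L (default 50).
#' @param c_max,c_min Comfort-zone decay endpoints (defaults 1 and 1e-5).
#' @param f,l Social-force intensity and length scale (defaults 0.5 and 1.5).
#' @param seed Integer seed for the uniform initialization.
#' @return List of class `goa_config`.
#' @export
goa_config <- function(bounds, n_pop = 30L, iterations = 50L,
                       c_max = 1, c_min = 1e-5, f = 0.5, l = 1.5,
                       seed = 1L) {
  stopifnot(is.data.frame(bounds), all(c("lo", "hi") %in% names(bounds)))
  if (is.null(bounds$kind)) bounds$kind <- "continuous"
  stopifnot(all(bounds$kind %in% c("continuous", "integer", "log")))
  if (any(bounds$lo >= bounds$hi)) {
    stop("each dimension needs lo < hi", call. = FALSE)
  }
  if (any(bounds$kind == "log" & bounds$lo <= 0)) {
    stop("log dimensions need positive bounds", call. = FALSE)
  }
  if (n_pop < 2) stop("population size must be >= 2", call. = FALSE)
  if (!(c_max > c_min && c_min > 0)) {
    stop("need c_max > c_min > 0", call. = FALSE)
  }
  structure(list(bounds = bounds, n_pop = as.integer(n_pop),
                 iterations = as.integer(iterations),
                 c_max = c_max, c_min = c_min, f = f, l = l,
                 seed = as.integer(seed)),
            class = "goa_config")
}

#' Social force between two grasshoppers
#'
#' `s(r) = f * exp(-r / l) - exp(-r)`: repulsive at short range (s < 0),
#' attractive at intermediate range, vanishing as r grows. With the default
#' `f = 0.5`, `l = 1.5` the comfort distance (root of s) sits near r = 2.079.
#'
#' @param r Nonnegative distance(s).
#' @param f Attraction intensity (default 0.5).
#' @param l Attractive length scale (default 1.5).
#' @return Numeric vector of forces.
#' @examples
#' social_force(0)          # -0.5: pure repulsion at contact
#' social_force(2.079)      # ~0: comfort distance
#' @export
social_force <- function(r, f = 0.5, l = 1.5) {
  if (any(r < 0)) stop("distance must be nonnegative", call. = FALSE)
  f * exp(-r / l) - exp(-r)
}

#' Comfort-zone coefficient at an iteration
#'
#' Linear decay `c(t) = c_max - t * (c_max - c_min) / L`, strictly decreasing
#' from `c_max` at t = 0 to `c_min` at t = L.
#'
#' @param t Iteration index, 0 <= t <= L.
#' @param config A [goa_config()].
#' @return The coefficient c.
#' @export
comfort_coefficient <- function(t, config) {
  L <- config$iterations
  if (any(t < 0 | t > L)) {
    stop("iteration must lie in [0, L]", call. = FALSE)
  }
  config$c_max - t * (config$c_max - config$c_min) / L
}

# internal search space: log dims are log10-transformed
.goa_internal_bounds <- function(bounds) {
  lo <- bounds$lo; hi <- bounds$hi
  is_log <- bounds$kind == "log"
  lo[is_log] <- log10(lo[is_log])
  hi[is_log] <- log10(hi[is_log])
  list(lo = lo, hi = hi, is_log = is_log,
       is_int = bounds$kind == "integer")
}

# map internal positions (matrix N x d) to user space
.goa_decode <- function(pos, ib) {
  out <- pos
  if (any(ib$is_log)) out[, ib$is_log] <- 10^out[, ib$is_log]
  out
}

.goa_clamp <- function(pos, ib) {
  pos <- pmin(pmax(pos, matrix(ib$lo, nrow(pos), ncol(pos), byrow = TRUE)),
              matrix(ib$hi, nrow(pos), ncol(pos), byrow = TRUE))
  if (any(ib$is_int)) {
    pos[, ib$is_int] <- round(pos[, ib$is_int])
  }
  pos
}

#' Initialize a GOA swarm
#'
#' Draws `n_pop` positions uniformly within the bounds (log dimensions in
#' log space), evaluates the objective, and records the incumbent best.
#'
#' @param objective Function of a numeric vector (user space) returning a
#'   scalar fitness to minimize.
#' @param config A [goa_config()].
#' @return List of class `goa_swarm` with `positions` (internal space),
#'   `fitness`, `best_position` (user space), `best_fitness`, `trace`.
#' @export
goa_init_swarm <- function(objective, config) {
  ib <- .goa_internal_bounds(config$bounds)
  d <- length(ib$lo)
  pos <- with_seed(config$seed, {
    matrix(stats::runif(config$n_pop * d), config$n_pop, d)
  })
  pos <- sweep(sweep(pos, 2, ib$hi - ib$lo, "*"), 2, ib$lo, "+")
  pos <- .goa_clamp(pos, ib)
  fit <- .goa_evaluate(objective, pos, ib)
  best <- which.min(fit)
  structure(list(positions = pos, fitness = fit,
                 best_internal = pos[best, ],
                 best_position = drop(.goa_decode(pos[best, , drop = FALSE],
                                                  ib)),
                 best_fitness = fit[best],
                 trace = fit[best]),
            class = "goa_swarm")
}

.goa_evaluate <- function(objective, pos, ib) {
  user <- .goa_decode(pos, ib)
  apply(user, 1, function(x) {
    v <- tryCatch(objective(x), error = function(e) Inf)
    if (!is.finite(v)) {
      warning("objective returned a non-finite value; candidate discarded",
              call. = FALSE)
      v <- Inf
    }
    v
  })
}

#' One GOA position update
#'
#' Moves every grasshopper by the comfort-scaled sum of pairwise social
#' forces plus attraction to the incumbent best:
#' `x_i <- c * sum_j c * (hi - lo)/2 * s(d_norm) * (x_j - x_i)/d_ij + best`.
#' Pairwise distances are normalized into \[1, 4) via `1 + (d mod 3)` before
#' the force kernel so the swarm does not stall in the kernel's flat tail;
#' coincident pairs (d = 0) contribute nothing. Positions are clamped to the
#' bounds and integer dimensions rounded after the update. The update is
#' deterministic given the swarm.
#'
#' @param swarm A `goa_swarm`.
#' @param c Comfort-zone coefficient for this iteration.
#' @param config The `goa_config`.
#' @param objective The objective being minimized (used to refresh fitness
#'   and the incumbent).
#' @return The updated `goa_swarm`.
#' @export
update_positions <- function(swarm, c, config, objective) {
  stopifnot(inherits(swarm, "goa_swarm"))
  ib <- .goa_internal_bounds(config$bounds)
  pos <- swarm$positions
  n <- nrow(pos); d <- ncol(pos)
  half_range <- (ib$hi - ib$lo) / 2
  dist <- as.matrix(stats::dist(pos))
  newpos <- matrix(0, n, d)
  for (i in seq_len(n)) {
    diffs <- sweep(pos, 2, pos[i, ], "-")        # x_j - x_i
    dij <- dist[i, ]
    ok <- dij > 0
    if (any(ok)) {
      s <- social_force(1 + (dij[ok] %% 3), config$f, config$l)
      unit <- diffs[ok, , drop = FALSE] / dij[ok]
      contrib <- (c * s) * unit                   # recycled over columns
      social <- colSums(contrib) * half_range
    } else {
      social <- numeric(d)
    }
    newpos[i, ] <- c * social + swarm$best_internal
  }
  newpos <- .goa_clamp(newpos, ib)
  fit <- .goa_evaluate(objective, newpos, ib)
  swarm$positions <- newpos
  swarm$fitness <- fit
  if (min(fit) < swarm$best_fitness) {
    b <- which.min(fit)
    swarm$best_fitness <- fit[b]
    swarm$best_internal <- newpos[b, ]
    swarm$best_position <- drop(.goa_decode(newpos[b, , drop = FALSE], ib))
  }
  swarm$trace <- c(swarm$trace, swarm$best_fitness)
  swarm
}

#' Minimize an objective with the Grasshopper Optimization Algorithm
#'
#' Runs `iterations` updates from a seeded uniform initialization and returns
#' the incumbent best. The best-so-far trace is nonincreasing by construction.
#'
#' @inheritParams goa_init_swarm
#' @param log_file Optional CSV path receiving `(iteration, c, best_fitness)`.
#' @return List with `par` (best position, user space), `value` (best
#'   fitness), `trace` (length `iterations + 1`) and `swarm` (final state).
#' @examples
#' cfg <- goa_config(data.frame(lo = c(-5, -5), hi = c(5, 5)),
#'                   n_pop = 20, iterations = 50, seed = 7)
#' res <- goa_optimize(function(x) sum(x^2), cfg)
#' res$value
#' @export
goa_optimize <- function(objective, config, log_file = NULL) {
  swarm <- goa_init_swarm(objective, config)
  log_rows <- NULL
  for (t in seq_len(config$iterations)) {
    cc <- comfort_coefficient(t, config)
    swarm <- update_positions(swarm, cc, config, objective)
    if (!is.null(log_file)) {
      log_rows <- rbind(log_rows,
                        data.frame(iteration = t, c = cc,
                                   best_fitness = swarm$best_fitness))
    }
  }
  if (!is.null(log_file)) utils::write.csv(log_rows, log_file,
                                           row.names = FALSE)
  list(par = swarm$best_position, value = swarm$best_fitness,
       trace = swarm$trace, swarm = swarm)
}

#' Default hyperparameter search space for tuning the yield network
#'
#' Four knobs of the training recipe and architecture: learning rate
#' (log-scaled, 1e-5 to 1e-2), dropout rate (0 to 0.5), batch size (integer,
#' 16 to 128) and convolution channels (integer, 64 to 256).
#'
#' @return A bounds data frame for [goa_config()], with row names naming the
#'   dimensions.
#' @export
gcba_search_space <- function() {
  data.frame(
    lo = c(1e-5, 0, 16, 64),
    hi = c(1e-2, 0.5, 128, 256),
    kind = c("log", "continuous", "integer", "integer"),
    row.names = c("lr", "dropout", "batch_size", "conv_channels")
  )
}
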