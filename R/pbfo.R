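# Polar-bear foraging optimization: a population metaheuristic over a mixed
# (continuous / discrete-set / categorical) hyperparameter space, alternating
# a roaming (exploration) update toward the incumbent plus a differential
# term, and a hunting (exploitation) contraction onto the incumbent.

#' Define one dimension of a hyperparameter search space
#'
#' @param name Dimension name.
#' @param kind `"continuous"`, `"discrete"` (snap to a value set) or
#'   `"categorical"` (index into `values`).
#' @param bounds Length-2 numeric bounds (continuous dims).
#' @param values Numeric value set (discrete) or character levels
#'   (categorical).
#' @param scale `"linear"` or `"log"` (continuous dims only; log dims search
#'   in log space).
#' @return A `"space_dim"` object.
#' @export
space_dim <- function(name, kind = c("continuous", "discrete", "categorical"),
                      bounds = NULL, values = NULL, scale = c("linear", "log")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (kind == "continuous") {
    stopifnot(length(bounds) == 2, all(is.finite(bounds)), bounds[1] < bounds[2])
    if (scale == "log") stopifnot(bounds[1] > 0)
  } else {
    stopifnot(length(values) >= 1)
  }
  structure(list(name = name, kind = kind, bounds = bounds, values = values,
                 scale = scale), class = "space_dim")
}

#' The default hyperparameter search space
#'
#' Learning rate and weight decay on a log scale, batch size and filter
#' count as discrete sets, optimizer as a categorical choice, dropout, the
#' three composite-loss weights, momentum and the learning-rate decay step.
#'
#' @return List of [space_dim()] objects (a `"search_space"`).
#' @export
default_search_space <- function() {
  structure(list(
    space_dim("learning_rate", "continuous", c(1e-5, 1e-2), scale = "log"),
    space_dim("batch_size", "discrete", values = c(8, 16, 32, 64)),
    space_dim("weight_decay", "continuous", c(1e-6, 1e-2), scale = "log"),
    space_dim("dropout", "continuous", c(0.1, 0.5)),
    space_dim("base_filters", "discrete", values = c(32, 64, 128, 256)),
    space_dim("optimizer", "categorical", values = c("adam", "sgd", "rmsprop")),
    space_dim("w_bce", "continuous", c(0.1, 0.9)),
    space_dim("w_dice", "continuous", c(0.1, 0.9)),
    space_dim("w_focal", "continuous", c(0.1, 0.9)),
    space_dim("lr_decay_step", "discrete", values = c(5, 10, 20)),
    space_dim("momentum", "continuous", c(0.8, 0.99))
  ), class = "search_space")
}

# Latent-space bounds: log dims live in log10 space, discrete dims span
# their value range, categorical dims live in [0, K).
latent_bounds <- function(space) {
  t(vapply(space, function(d) {
    switch(d$kind,
      continuous = if (d$scale == "log") log10(d$bounds) else d$bounds,
      discrete = range(d$values),
      categorical = c(0, length(d$values)))
  }, numeric(2)))
}

#' PBFO run configuration
#'
#' @param m Population size (>= 4).
#' @param t_max Maximum iterations (>= 1).
#' @param eps Fitness-improvement termination threshold (checked after a
#'   5-iteration grace period).
#' @param alpha,beta,gamma Length-2 schedule endpoints `(start, end)` of the
#'   attraction, diffusion and contraction coefficients; each is linearly
#'   interpolated over iterations.
#' @param seed Integer seed.
#' @return A `"pbfo_config"` object.
#' @export
pbfo_config <- function(m = 20L, t_max = 50L, eps = 1e-6,
                        alpha = c(1.0, 0.2), beta = c(0.8, 0.1),
                        gamma = c(0.1, 0.9), seed = 1L) {
  stopifnot(m >= 4, t_max >= 1, eps >= 0,
            all(c(alpha, beta, gamma) >= 0), all(c(alpha, beta, gamma) <= 2))
  structure(list(m = as.integer(m), t_max = as.integer(t_max), eps = eps,
                 alpha = alpha, beta = beta, gamma = gamma,
                 seed = as.integer(seed)), class = "pbfo_config")
}

#' Initialize the candidate population
#'
#' Each latent coordinate is drawn uniformly within its dimension bounds
#' (log10 space for log-scaled dims).
#'
#' @param space A search space (list of [space_dim()]).
#' @param cfg A [pbfo_config()].
#' @return m x n latent matrix (one candidate per row).
#' @export
init_population <- function(space, cfg) {
  if (cfg$m < 4) stop("init_population: population size must be >= 4")
  lb <- latent_bounds(space)
  with_seed(cfg$seed, {
    sapply(seq_along(space), function(j)
      stats::runif(cfg$m, lb[j, 1], lb[j, 2]))
  })
}

#' Decode a latent vector into a hyperparameter assignment
#'
#' Continuous dims pass through (log dims are exponentiated), discrete dims
#' snap to the nearest listed value, categorical dims floor the latent into
#' an index (clamped to the valid range).
#'
#' @param latent Numeric latent vector.
#' @param space The search space.
#' @return Named list of decoded hyperparameter values.
#' @export
decode_candidate <- function(latent, space) {
  out <- lapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- latent[j]
    switch(d$kind,
      continuous = {
        v <- min(max(v, latent_bounds(space)[j, 1]), latent_bounds(space)[j, 2])
        if (d$scale == "log") 10^v else v
      },
      discrete = d$values[which.min(abs(d$values - v))],
      categorical = d$values[min(max(floor(v), 0), length(d$values) - 1) + 1])
  })
  names(out) <- vapply(space, `[[`, "", "name")
  out
}

#' Roaming (exploration) update of the whole population
#'
#' `H_i <- H_i + alpha * R1 * (H_best - H_i) + beta * R2 * (H_j - H_k)` with
#' per-coordinate `R1, R2 ~ U(0, 1)` and random distinct partners
#' `j != k != i`, clamped to the latent bounds.
#'
#' @param pop m x n latent matrix.
#' @param best Latent vector of the incumbent.
#' @param alpha_t,beta_t Current schedule values.
#' @param space The search space (for bounds).
#' @param r1,r2 Optional fixed values replacing the per-coordinate
#'   `U(0, 1)` draws (scalars; used to exercise the closed-form limits of
#'   the update).
#' @return Updated population matrix.
#' @export
exploration_step <- function(pop, best, alpha_t, beta_t, space,
                             r1 = NULL, r2 = NULL) {
  m <- nrow(pop)
  if (m < 3) stop("exploration_step: population must have at least 3 members")
  lb <- latent_bounds(space)
  n <- ncol(pop)
  old <- pop
  for (i in seq_len(m)) {
    jk <- sample(setdiff(seq_len(m), i), 2)
    r1v <- if (is.null(r1)) stats::runif(n) else rep(r1, n)
    r2v <- if (is.null(r2)) stats::runif(n) else rep(r2, n)
    pop[i, ] <- pop[i, ] + alpha_t * r1v * (best - pop[i, ]) +
      beta_t * r2v * (old[jk[1], ] - old[jk[2], ])
  }
  pmin(pmax(pop, matrix(lb[, 1], m, n, byrow = TRUE)),
       matrix(lb[, 2], m, n, byrow = TRUE))
}

#' Hunting (exploitation) contraction of one candidate
#'
#' `H_i <- H_i + gamma * (H_best - H_i)`, clamped to bounds.
#'
#' @param latent Candidate latent vector.
#' @param best Incumbent latent vector.
#' @param gamma_t Contraction coefficient in `(0, 1]`.
#' @param space The search space.
#' @return Updated latent vector.
#' @export
exploitation_step <- function(latent, best, gamma_t, space) {
  lb <- latent_bounds(space)
  v <- latent + gamma_t * (best - latent)
  pmin(pmax(v, lb[, 1]), lb[, 2])
}

#' Linear coefficient schedules
#'
#' Interpolates the `(start, end)` endpoints of alpha, beta and gamma at
#' iteration `t` and returns the exploitation probability `t / t_max`.
#'
#' @param t Iteration, `0 <= t <= t_max`.
#' @param cfg A [pbfo_config()].
#' @return List with `alpha`, `beta`, `gamma`, `p_exploit`.
#' @export
pbfo_schedule <- function(t, cfg) {
  stopifnot(t >= 0, t <= cfg$t_max)
  f <- t / cfg$t_max
  lerp <- function(ab) ab[1] + f * (ab[2] - ab[1])
  list(alpha = lerp(cfg$alpha), beta = lerp(cfg$beta), gamma = lerp(cfg$gamma),
       p_exploit = f)
}

#' Termination test
#'
#' Stops at `t >= t_max`, or when the best-fitness improvement falls below
#' `eps` after a 5-iteration grace period.
#'
#' @param best_history Numeric vector of best fitness per iteration.
#' @param t Current iteration.
#' @param cfg A [pbfo_config()].
#' @return Logical.
#' @export
check_termination <- function(best_history, t, cfg) {
  stopifnot(length(best_history) >= 1)
  if (t >= cfg$t_max) return(TRUE)
  h <- length(best_history)
  if (t > 5 && h >= 2 &&
      abs(best_history[h] - best_history[h - 1]) < cfg$eps) return(TRUE)
  FALSE
}

#' Run the polar-bear foraging optimizer
#'
#' Per iteration each candidate exploits (contracts toward the incumbent)
#' with probability `t / t_max` and otherwise takes a roaming exploration
#' move (attraction to the incumbent plus a differential diversity term).
#' Moves are greedy — a candidate keeps its new position only when the
#' re-evaluated fitness does not drop — and the incumbent is updated
#' asynchronously, so later candidates in the same iteration contract onto
#' the freshest best. The returned optimum is the argmax over every
#' evaluation ever made. Maximizes `fitness_fn`.
#'
#' @param space A search space (list of [space_dim()]).
#' @param fitness_fn Function taking a decoded hyperparameter list (named
#'   values) and returning a scalar fitness to maximize; errors and
#'   non-finite returns are recorded as fitness 0.
#' @param cfg A [pbfo_config()].
#' @return List with `best` (decoded assignment), `best_latent`,
#'   `best_fitness`, and `history` (data frame: iteration, best_fitness,
#'   mean_fitness).
#' @export
run_pbfo <- function(space, fitness_fn, cfg = pbfo_config()) {
  eval_one <- function(latent) {
    f <- tryCatch(fitness_fn(decode_candidate(latent, space)),
                  error = function(e) 0)
    if (!is.finite(f)) 0 else f
  }
  with_seed(cfg$seed, {
    lb <- latent_bounds(space)
    n <- length(space)
    pop <- sapply(seq_along(space), function(j)
      stats::runif(cfg$m, lb[j, 1], lb[j, 2]))
    fit <- apply(pop, 1, eval_one)
    best_i <- which.max(fit)
    best_latent <- pop[best_i, ]
    best_fit <- fit[best_i]
    hist <- data.frame(iteration = 0L, best_fitness = best_fit,
                       mean_fitness = mean(fit))
    t <- 0L
    while (!check_termination(hist$best_fitness, t, cfg)) {
      t <- t + 1L
      sc <- pbfo_schedule(t, cfg)
      for (i in seq_len(cfg$m)) {
        if (stats::runif(1) < sc$p_exploit) {
          cand <- exploitation_step(pop[i, ], best_latent, sc$gamma, space)
        } else {
          jk <- sample(setdiff(seq_len(cfg$m), i), 2)
          r1 <- stats::runif(n)
          r2 <- stats::runif(n)
          cand <- pop[i, ] + sc$alpha * r1 * (best_latent - pop[i, ]) +
            sc$beta * r2 * (pop[jk[1], ] - pop[jk[2], ])
          cand <- pmin(pmax(cand, lb[, 1]), lb[, 2])
        }
        f <- eval_one(cand)
        if (f >= fit[i]) { # greedy replacement
          pop[i, ] <- cand
          fit[i] <- f
        }
        if (f > best_fit) {
          best_fit <- f
          best_latent <- cand
        }
      }
      hist <- rbind(hist, data.frame(iteration = t, best_fitness = best_fit,
                                     mean_fitness = mean(fit)))
    }
    list(best = decode_candidate(best_latent, space),
         best_latent = best_latent, best_fitness = best_fit, history = hist)
  })
}
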