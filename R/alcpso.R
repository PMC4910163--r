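## Particle swarm optimization with an aging leader and challengers.
##
## A standard inertia-weight swarm is attracted by personal bests and by a
## leader.  The leader carries an age and a lifespan: every generation its
## "leading power" is assessed (did the best-ever solution improve? did
## the personal bests improve in aggregate? did the leader's own fitness
## improve?) and its lifespan adjusted (+2 / +1 / 0 / -1).  When the age
## exceeds the lifespan, a challenger is generated by mutating each leader
## coordinate with probability 1/d (uniform redraw within bounds); the
## challenger guides the swarm for a fixed number of trial generations and
## replaces the leader only if it shows leading power during the trial.
## Aging keeps a stale leader from trapping the swarm in a local optimum
## while preserving the fast convergence of plain PSO (which is available
## via aging = FALSE and serves as a reference baseline).

#' Control parameters for the swarm optimizer
#'
#' @param swarm_size Number of particles (>= 2).
#' @param inertia Velocity inertia weight (0 < w < 1).
#' @param c1,c2 Cognitive / social acceleration coefficients.
#' @param lifespan Initial leader lifespan (generations).
#' @param challenger_trials Generations a challenger leads on trial.
#' @param max_iter Maximum number of generations.
#' @param stagnation Stop after this many generations without improvement
#'   of the best-ever fitness (set to \code{Inf} to disable).
#' @param vmax_frac Velocity clamp, as a fraction of each dimension's range.
#' @param aging Use the aging-leader mechanism; \code{FALSE} gives plain
#'   global-best PSO with the same updates.
#' @param seed Integer seed; the run is fully deterministic given the seed.
#' @return A list of class \code{"pso_control"}.
#' @export
pso_control <- function(swarm_size = 20L, inertia = 0.4, c1 = 2, c2 = 2,
                        lifespan = 60L, challenger_trials = 2L,
                        max_iter = 100L, stagnation = 50L,
                        vmax_frac = 0.5, aging = TRUE, seed = 1L) {
  stopifnot(swarm_size >= 2L, inertia > 0, inertia < 1, max_iter >= 0L,
            lifespan >= 1L, challenger_trials >= 1L)
  structure(list(swarm_size = as.integer(swarm_size), inertia = inertia,
                 c1 = c1, c2 = c2, lifespan = as.integer(lifespan),
                 challenger_trials = as.integer(challenger_trials),
                 max_iter = as.integer(max_iter), stagnation = stagnation,
                 vmax_frac = vmax_frac, aging = isTRUE(aging),
                 seed = as.integer(seed)),
            class = "pso_control")
}

#' Maximize an objective with the aging-leader particle swarm
#'
#' @param objective Function of a numeric vector of length \code{d},
#'   returning a scalar fitness to maximize.
#' @param lower,upper Per-dimension bounds (scalars are recycled to
#'   length \code{d}).
#' @param d Problem dimension.
#' @param control A \code{\link{pso_control}} list.
#' @param init Optional matrix (d x k) of initial positions for the first
#'   k particles, e.g. a known baseline such as the all-zero delta vector.
#' @return List with \code{par} (best position found), \code{value} (its
#'   fitness), \code{trace} (best-ever fitness per generation) and
#'   \code{evaluations} (objective call count).
#' @export
#' @examples
#' res <- alc_pso(function(x) -sum(x^2), -5, 5, d = 2,
#'                control = pso_control(max_iter = 50, seed = 1))
#' res$value  # close to 0
alc_pso <- function(objective, lower, upper, d,
                    control = pso_control(), init = NULL) {
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  if (any(lower >= upper)) stop("invalid bounds: lower must be < upper")
  S <- control$swarm_size
  vmax <- control$vmax_frac * (upper - lower)
  n_eval <- 0L
  evalfn <- function(x) {
    n_eval <<- n_eval + 1L
    objective(x)
  }

  with_seed(control$seed, {
    X <- matrix(stats::runif(d * S, lower, upper), d, S)
    if (!is.null(init)) {
      init <- as.matrix(init)
      k <- min(ncol(init), S)
      X[, seq_len(k)] <- pmin(pmax(init[, seq_len(k), drop = FALSE], lower), upper)
    }
    V <- matrix(stats::runif(d * S, -vmax, vmax), d, S)
    fit <- apply(X, 2L, evalfn)
    pbest <- X
    pbest_fit <- fit

    gbest_i <- which.max(fit)
    gbest <- X[, gbest_i]
    gbest_fit <- fit[gbest_i]

    leader <- gbest
    leader_fit <- gbest_fit
    age <- 0L
    lifespan <- control$lifespan
    trial_left <- 0L
    trial_ok <- FALSE
    saved_leader <- NULL
    saved_leader_fit <- NULL

    trace <- numeric(control$max_iter)
    stagnant <- 0L
    iters <- 0L

    for (it in seq_len(control$max_iter)) {
      old_gbest <- gbest_fit
      old_psum <- sum(pbest_fit)
      old_leader_fit <- leader_fit

      r1 <- matrix(stats::runif(d * S), d, S)
      r2 <- matrix(stats::runif(d * S), d, S)
      attractor <- if (control$aging) leader else gbest
      V <- control$inertia * V +
        control$c1 * r1 * (pbest - X) +
        control$c2 * r2 * (attractor - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, lower), upper)
      fit <- apply(X, 2L, evalfn)

      improved <- fit > pbest_fit
      if (any(improved)) {
        pbest[, improved] <- X[, improved]
        pbest_fit[improved] <- fit[improved]
      }
      best_i <- which.max(fit)
      if (fit[best_i] > leader_fit) {
        leader <- X[, best_i]
        leader_fit <- fit[best_i]
      }
      if (max(pbest_fit) > gbest_fit) {
        gbest_i <- which.max(pbest_fit)
        gbest <- pbest[, gbest_i]
        gbest_fit <- pbest_fit[gbest_i]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }

      if (control$aging) {
        d_gbest <- gbest_fit - old_gbest
        d_psum <- sum(pbest_fit) - old_psum
        d_self <- leader_fit - old_leader_fit
        if (trial_left > 0L) {
          ## challenger on trial: accept as soon as it shows leading power
          if (d_gbest > 0 || d_psum > 0) trial_ok <- TRUE
          trial_left <- trial_left - 1L
          if (trial_left == 0L) {
            if (trial_ok) {
              age <- 0L
              lifespan <- control$lifespan
            } else {
              leader <- saved_leader
              leader_fit <- saved_leader_fit
              age <- 0L
            }
          }
        } else {
          if (d_gbest > 0) {
            lifespan <- lifespan + 2L
          } else if (d_psum > 0) {
            lifespan <- lifespan + 1L
          } else if (d_self > 0) {
            ## leading power on itself only: lifespan unchanged
          } else {
            lifespan <- max(1L, lifespan - 1L)
          }
          age <- age + 1L
          if (age >= lifespan) {
            saved_leader <- leader
            saved_leader_fit <- leader_fit
            challenger <- leader
            mutate <- stats::runif(d) < 1 / d
            if (!any(mutate)) mutate[sample.int(d, 1L)] <- TRUE
            challenger[mutate] <- stats::runif(sum(mutate),
                                               lower[mutate], upper[mutate])
            leader <- challenger
            leader_fit <- evalfn(challenger)
            if (leader_fit > gbest_fit) {
              gbest <- challenger
              gbest_fit <- leader_fit
              stagnant <- 0L
            }
            trial_left <- control$challenger_trials
            trial_ok <- FALSE
          }
        }
      }

      trace[it] <- gbest_fit
      iters <- it
      if (stagnant >= control$stagnation) break
    }
  })

  list(par = gbest, value = gbest_fit,
       trace = trace[seq_len(iters)], evaluations = n_eval)
}
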