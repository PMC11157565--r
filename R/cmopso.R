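#' Nonlinearly decreasing inertia weight
#'
#' Inertia schedule for the swarm velocity update:
#' \deqn{w(t) = (w_{max} - w_{min})\,(t/T - 1)^2 + w_{min}.}
#' The weight starts at `w_max`, ends at `w_min`, and decreases along a
#' convex quadratic, so early iterations keep momentum (exploration) and
#' late iterations damp it (convergence).
#'
#' @param t Iteration, `0 <= t <= T`.
#' @param T_max Total number of iterations.
#' @param w_max,w_min Schedule endpoints (defaults 0.9 and 0.4).
#' @return The inertia weight at iteration `t`.
#' @export
inertia_weight <- function(t, T_max, w_max = 0.9, w_min = 0.4) {
  if (any(t < 0) || any(t > T_max)) abort("`t` must lie in [0, T_max].")
  if (w_max <= w_min) abort("`w_max` must exceed `w_min`.")
  (w_max - w_min) * (t / T_max - 1)^2 + w_min
}

#' Linearly scheduled acceleration factors
#'
#' Cognitive (`c1`) and social (`c2`) acceleration coefficients as linear
#' ramps over the run:
#' \deqn{c_1(t) = c_{1f} + (c_{1i} - c_{1f})\,t/T, \qquad
#'       c_2(t) = c_{2f} + (c_{2i} - c_{2f})\,t/T,}
#' so with the defaults `c1` falls 2.75 to 1.25 (strong self-attraction
#' early, weak late) while `c2` rises 0.5 to 2.25 (swarm attraction grows
#' as the archive matures).
#'
#' `literal_c2 = TRUE` switches the second line to
#' \eqn{c_2(t) = c_{2f} + (c_{2f} - c_{2i})\,t/T}, a variant whose ramp
#' runs outside the intended 0.5–2.25 range (it reaches `2 c2f - c2i` at
#' `t = T`); it is provided for comparison only and is not the default.
#'
#' @inheritParams inertia_weight
#' @param c1i,c1f,c2i,c2f Ramp parameters (defaults 1.25, 2.75, 2.25, 0.5).
#' @param literal_c2 Use the alternative (sign-flipped) `c2` ramp.
#' @return Named numeric vector `c(c1 = ..., c2 = ...)`.
#' @export
acceleration_factors <- function(t, T_max, c1i = 1.25, c1f = 2.75,
                                 c2i = 2.25, c2f = 0.5,
                                 literal_c2 = FALSE) {
  if (any(t < 0) || any(t > T_max)) abort("`t` must lie in [0, T_max].")
  c1 <- c1f + (c1i - c1f) * (t / T_max)
  c2 <- if (literal_c2) {
    c2f + (c2f - c2i) * (t / T_max)
  } else {
    c2f + (c2i - c2f) * (t / T_max)
  }
  c(c1 = c1, c2 = c2)
}

#' Decode a particle position into a feature subset
#'
#' A particle lives in the continuous unit cube, one dimension per
#' candidate feature; dimensions whose position exceeds `threshold` are
#' "on". An all-off particle is repaired to the single dimension with the
#' largest position so the decoded subset is never empty.
#'
#' @param position Numeric vector in `[0, 1]`.
#' @param threshold Decoding cutoff in `(0, 1)` (default 0.6).
#' @return Integer vector of selected dimensions (1-based), always
#'   nonempty.
#' @export
decode_particle <- function(position, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  sel <- which(position > threshold)
  if (length(sel) == 0) sel <- which.max(position)
  sel
}

# Velocity update (one particle): v' = w v + c1 r1 (pbest - x) + c2 r2
# (leader - x), fresh r1, r2 ~ U(0,1) per dimension, clamped to +/- v_max.
update_velocity <- function(v, x, pbest, leader, w, c1, c2, v_max = 0.5,
                            r1 = runif(length(v)), r2 = runif(length(v))) {
  vnew <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (leader - x)
  pmin(pmax(vnew, -v_max), v_max)
}

# Position update: add velocity, clip to [0,1]; a clipped dimension has its
# velocity zeroed so the particle does not push against the wall.
update_position <- function(x, v) {
  xn <- x + v
  clipped <- xn < 0 | xn > 1
  list(x = pmin(pmax(xn, 0), 1), v = ifelse(clipped, 0, v))
}

# pbest replacement: new dominates -> take it; old dominates -> keep; mutual
# non-dominance -> coin flip.
pbest_replace <- function(old_obj, new_obj) {
  if (dominates(new_obj, old_obj)) return(TRUE)
  if (dominates(old_obj, new_obj)) return(FALSE)
  runif(1) < 0.5
}

# Subset objective (f1 = size, f2 = CV PLS RMSE), memoized per run so a
# subset is only ever cross-validated once and f2 is a deterministic
# function of the subset.
make_evaluator <- function(X, y, folds, ncomp, shuffle_seed, aggregate) {
  memo <- new.env(parent = emptyenv())
  count <- 0L
  eval_subset <- function(subset) {
    key <- paste(subset, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    count <<- count + 1L
    rmse <- cv_pls(X[, subset, drop = FALSE], y, folds,
                   min(ncomp, length(subset)), shuffle_seed, aggregate,
                   quiet = TRUE)$rmse
    obj <- c(length(subset), rmse)
    memo[[key]] <- obj
    obj
  }
  list(eval = eval_subset, n_unique = function() count)
}

#' Multi-objective particle swarm over a candidate feature set
#'
#' Searches the subsets of a candidate feature set for Pareto-optimal
#' trade-offs between subset size (`f1`) and k-fold cross-validated PLS
#' RMSE (`f2`), both minimized. Particles are continuous points in the
#' unit cube (one dimension per candidate feature) decoded by threshold
#' (see [decode_particle()]); velocities follow the classic update with a
#' per-particle leader drawn from a bounded Pareto archive by
#' adaptive-grid roulette, a nonlinearly decreasing inertia weight
#' ([inertia_weight()]) and linearly scheduled acceleration factors
#' ([acceleration_factors()]). The archive keeps at most `archive_size`
#' mutually non-dominated solutions, truncated by crowding distance.
#'
#' `optimizer = "mopso"` runs the identical loop with constant
#' coefficients (`w = w_max`, `c1 = c2 = 2`) — the unscheduled baseline.
#'
#' Fold assignment is fixed once per run (`shuffle_seed`), and subset
#' evaluations are memoized, so `f2` is a deterministic function of the
#' subset and the whole run is reproducible from `seed`.
#'
#' @inheritParams kfold_pls_rmse
#' @param features Character vector naming the candidate features to
#'   search over (default: all feature columns of `data`).
#' @param optimizer `"cmopso"` (scheduled coefficients) or `"mopso"`
#'   (constant coefficients).
#' @param iterations Number of swarm iterations `T` (default 300).
#' @param pop_size Number of particles (default 100).
#' @param archive_size Archive capacity (default 50).
#' @param mesh Grid divisions per objective for leader selection
#'   (default 20).
#' @param threshold Position decode cutoff (default 0.6).
#' @param w_max,w_min,c1i,c1f,c2i,c2f Schedule parameters; see
#'   [inertia_weight()] and [acceleration_factors()].
#' @param literal_c2 See [acceleration_factors()].
#' @param v_max Velocity clamp (default 0.5, half the position range).
#' @param seed Integer seed for the swarm's random draws; `NULL` leaves
#'   the generator state alone.
#'
#' @return An object of class `cmopso_result`: a list with `front` (a
#'   tibble with one row per archive member: `n_features`, `rmse`, and a
#'   `features` list-column), `history` (per-iteration archive size and
#'   best RMSE), `n_evaluations` (unique subsets cross-validated) and the
#'   configuration. Supports [tidy()], [glance()] and [autoplot()].
#' @export
cmopso <- function(data, target, features = NULL,
                   optimizer = c("cmopso", "mopso"),
                   iterations = 300, pop_size = 100, archive_size = 50,
                   mesh = 20, threshold = 0.6,
                   folds = 10, ncomp = 2, shuffle_seed = 0,
                   aggregate = c("fold_mean", "pooled"),
                   w_max = 0.9, w_min = 0.4,
                   c1i = 1.25, c1f = 2.75, c2i = 2.25, c2f = 0.5,
                   literal_c2 = FALSE, v_max = 0.5, seed = NULL) {
  optimizer <- match.arg(optimizer)
  aggregate <- match.arg(aggregate)
  parts <- split_target(data, {{ target }})
  X <- parts$X
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing) > 0) {
      abort(paste0("unknown feature(s): ", paste(head(missing, 3), collapse = ", ")))
    }
    X <- X[, features, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  run <- run_swarm(X, parts$y, optimizer, iterations, pop_size,
                   archive_size, mesh, threshold, folds, ncomp,
                   shuffle_seed, aggregate, w_max, w_min,
                   c1i, c1f, c2i, c2f, literal_c2, v_max)
  front <- tibble::tibble(
    n_features = as.integer(run$archive$obj[, 1]),
    rmse = run$archive$obj[, 2],
    features = lapply(run$archive$sets, function(s) colnames(X)[s]),
    position = run$archive$pos
  )
  front <- dplyr::arrange(front, .data$n_features, .data$rmse)
  structure(
    list(
      front = front,
      history = run$history,
      n_evaluations = run$n_evaluations,
      candidate_features = colnames(X),
      target = parts$target,
      config = list(
        optimizer = optimizer, iterations = iterations,
        pop_size = pop_size, archive_size = archive_size, mesh = mesh,
        threshold = threshold, folds = folds, ncomp = ncomp,
        shuffle_seed = shuffle_seed, aggregate = aggregate,
        w_max = w_max, w_min = w_min, c1i = c1i, c1f = c1f,
        c2i = c2i, c2f = c2f, literal_c2 = literal_c2, v_max = v_max,
        seed = seed
      )
    ),
    class = "cmopso_result"
  )
}

# Main loop on matrices; caller owns the RNG state.
run_swarm <- function(X, y, optimizer, iterations, pop_size, archive_size,
                      mesh, threshold, folds, ncomp, shuffle_seed,
                      aggregate, w_max, w_min, c1i, c1f, c2i, c2f,
                      literal_c2, v_max) {
  D <- ncol(X)
  ev <- make_evaluator(X, y, folds, ncomp, shuffle_seed, aggregate)

  pos <- matrix(runif(pop_size * D), pop_size, D)
  vel <- matrix(0, pop_size, D)
  sets <- apply(pos, 1, decode_particle, threshold = threshold, simplify = FALSE)
  obj <- t(vapply(sets, ev$eval, numeric(2)))
  pbest_pos <- pos
  pbest_obj <- obj

  archive <- new_archive(archive_size)
  archive <- archive_update(archive, obj, sets,
                            lapply(seq_len(pop_size), function(i) pos[i, ]))

  history <- matrix(0, iterations, 2)
  for (t in seq_len(iterations)) {
    if (optimizer == "cmopso") {
      w <- inertia_weight(t, iterations, w_max, w_min)
      cc <- acceleration_factors(t, iterations, c1i, c1f, c2i, c2f, literal_c2)
    } else {
      w <- w_max
      cc <- c(c1 = 2, c2 = 2)
    }
    for (i in seq_len(pop_size)) {
      leader <- archive$pos[[select_leader(archive, mesh)]]
      v <- update_velocity(vel[i, ], pos[i, ], pbest_pos[i, ], leader,
                           w, cc[["c1"]], cc[["c2"]], v_max)
      up <- update_position(pos[i, ], v)
      pos[i, ] <- up$x
      vel[i, ] <- up$v
    }
    sets <- apply(pos, 1, decode_particle, threshold = threshold, simplify = FALSE)
    obj <- t(vapply(sets, ev$eval, numeric(2)))
    for (i in seq_len(pop_size)) {
      if (pbest_replace(pbest_obj[i, ], obj[i, ])) {
        pbest_obj[i, ] <- obj[i, ]
        pbest_pos[i, ] <- pos[i, ]
      }
    }
    archive <- archive_update(archive, obj, sets,
                              lapply(seq_len(pop_size), function(i) pos[i, ]))
    history[t, ] <- c(nrow(archive$obj), min(archive$obj[, 2]))
  }

  list(
    archive = archive,
    history = tibble::tibble(
      iteration = seq_len(iterations),
      archive_size = as.integer(history[, 1]),
      best_rmse = history[, 2]
    ),
    n_evaluations = ev$n_unique()
  )
}

#' @export
print.cmopso_result <- function(x, ...) {
  cat("Pareto front (", x$config$optimizer, ", ",
      x$config$iterations, " iterations, ", x$config$pop_size,
      " particles)\n", sep = "")
  cat("  candidate set:", length(x$candidate_features), "features;",
      x$n_evaluations, "unique subsets evaluated\n")
  print(dplyr::select(x$front, "n_features", "rmse"))
  invisible(x)
}
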