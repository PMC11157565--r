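#' Pareto dominance between two objective vectors
#'
#' Under minimization, `a` dominates `b` when `a` is no worse in every
#' objective and strictly better in at least one. Equal vectors do not
#' dominate each other.
#'
#' @param a,b Numeric objective vectors of equal length (minimized).
#' @return `TRUE` if `a` dominates `b`.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) abort("objective vectors differ in length.")
  all(a <= b) && any(a < b)
}

as_objective_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  if (!is.numeric(points)) abort("objectives must be numeric.")
  points
}

#' Indices of the non-dominated points in a set
#'
#' Returns the positions of every point not Pareto-dominated (under
#' minimization) by any other point in the set. Duplicated points are all
#' retained: a copy never strictly beats its twin.
#'
#' @param points Numeric matrix or data frame, one row per point, one
#'   column per (minimized) objective.
#' @return Integer vector of row indices.
#' @export
non_dominated <- function(points) {
  P <- as_objective_matrix(points)
  n <- nrow(P)
  if (n == 0) return(integer(0))
  if (ncol(P) == 2) return(non_dominated_2d(P))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(P[j, ] <= P[i, ]) && any(P[j, ] < P[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

# Sweep-based filter for the two-objective case: sort by (f1, f2); a point
# is dominated iff a point with strictly smaller f1 has f2 no larger, or a
# point with equal f1 has strictly smaller f2. Exact duplicates survive.
non_dominated_2d <- function(P) {
  n <- nrow(P)
  o <- order(P[, 1], P[, 2])
  f1 <- P[o, 1]
  f2 <- P[o, 2]
  g <- cumsum(c(TRUE, f1[-1] != f1[-n]))
  gmin <- stats::ave(f2, g, FUN = min)
  umin <- gmin[!duplicated(g)]
  prev <- c(Inf, cummin(umin))[g] # min f2 over strictly smaller f1
  dominated <- (f2 >= prev) | (f2 > gmin)
  sort(o[!dominated])
}

#' Crowding distance of a Pareto front
#'
#' Per objective, points are sorted, the two extremes get `Inf`, and each
#' interior point gets the gap between its neighbours normalized by the
#' objective range; distances are summed over objectives. An objective
#' with zero range contributes 0 to every point. Larger distance means a
#' less crowded (more valuable) solution.
#'
#' @inheritParams non_dominated
#' @return Numeric vector of distances aligned with the rows of `points`.
#' @export
crowding_distance <- function(points) {
  P <- as_objective_matrix(points)
  n <- nrow(P)
  if (n == 0) abort("`points` must be nonempty.")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(P))) {
    v <- P[, k]
    rng <- max(v) - min(v)
    if (rng == 0) next # degenerate objective: contributes 0 everywhere
    ord <- order(v, seq_len(n))
    d[ord[c(1, n)]] <- Inf
    inner <- ord[2:(n - 1)]
    d[inner] <- d[inner] + (v[ord[3:n]] - v[ord[1:(n - 2)]]) / rng
  }
  d
}

# ---- bounded Pareto archive -------------------------------------------------
#
# Internal representation: obj = k x 2 matrix (n_features, rmse); sets =
# list of integer feature-index vectors; pos = list of position vectors
# that produced each entry; stamp = insertion order (later-inserted entries
# lose deterministic crowding ties during truncation).

new_archive <- function(capacity) {
  list(obj = matrix(numeric(0), 0, 2), sets = list(), pos = list(),
       stamp = integer(0), capacity = as.integer(capacity), counter = 0L)
}

archive_update <- function(archive, obj, sets, pos) {
  k_old <- nrow(archive$obj)
  obj_all <- rbind(archive$obj, obj)
  sets_all <- c(archive$sets, sets)
  pos_all <- c(archive$pos, pos)
  stamp_all <- c(archive$stamp, archive$counter + seq_len(nrow(obj)))
  archive$counter <- archive$counter + nrow(obj)

  keep <- non_dominated(obj_all)
  # collapse exact duplicates (same objectives AND same feature set);
  # equal objectives with different sets are distinct solutions and stay
  key <- vapply(keep, function(i) {
    paste(obj_all[i, 1], format(obj_all[i, 2], digits = 17),
          paste(sets_all[[i]], collapse = ","))
  }, character(1))
  keep <- keep[!duplicated(key)]

  obj_all <- obj_all[keep, , drop = FALSE]
  sets_all <- sets_all[keep]
  pos_all <- pos_all[keep]
  stamp_all <- stamp_all[keep]

  # truncate one at a time, recomputing crowding after each removal
  while (nrow(obj_all) > archive$capacity) {
    cd <- crowding_distance(obj_all)
    victims <- which(cd == min(cd))
    drop_i <- victims[which.max(stamp_all[victims])]
    obj_all <- obj_all[-drop_i, , drop = FALSE]
    sets_all <- sets_all[-drop_i]
    pos_all <- pos_all[-drop_i]
    stamp_all <- stamp_all[-drop_i]
  }

  archive$obj <- obj_all
  archive$sets <- sets_all
  archive$pos <- pos_all
  archive$stamp <- stamp_all
  archive$crowding <- if (nrow(obj_all) > 0) crowding_distance(obj_all) else numeric(0)
  archive
}

# Adaptive-grid roulette leader selection: objective space over the archive
# bounds (inflated slightly) is cut into divisions x divisions cells; a cell
# is drawn with weight 1/occupancy, then a uniform member of that cell.
select_leader <- function(archive, divisions = 20, inflation = 0.1) {
  k <- nrow(archive$obj)
  if (k == 0) abort("archive is empty.")
  if (k == 1) return(1L)
  cell <- integer(k)
  for (d in 1:2) {
    v <- archive$obj[, d]
    lo <- min(v); hi <- max(v)
    pad <- (hi - lo) * inflation / 2 + 1e-12
    edges <- seq(lo - pad, hi + pad, length.out = divisions + 1)
    cell <- cell * divisions +
      findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  }
  occ <- table(cell)
  w <- 1 / as.numeric(occ)
  chosen_cell <- names(occ)[sample.int(length(occ), 1, prob = w / sum(w))]
  members <- which(cell == as.integer(chosen_cell))
  members[sample.int(length(members), 1)]
}
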