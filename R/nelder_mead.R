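#' Options for the Nelder-Mead simplex search
#'
#' Coefficients and stopping rules for [nelder_mead()].  The defaults
#' mirror the long-standing simplex conventions popularised by MATLAB's
#' `fminsearch`: reflection 1, expansion 2, contraction 0.5, shrink 0.5,
#' both tolerances `1e-4`, and an initial simplex built by perturbing each
#' coordinate of the start point by 5% (absolute step `0.00025` for zero
#' coordinates).
#'
#' @param reflection,expansion,contraction,shrink simplex coefficients;
#'   all positive with `expansion > 1 > contraction`.
#' @param tol_x,tol_f termination tolerances on the simplex spread in
#'   coordinates and function values (both must be met).
#' @param max_evaluations evaluation budget; the search never calls the
#'   objective more than this many times.
#' @param simplex_scale relative perturbation for the initial simplex.
#' @param zero_step absolute perturbation used where a coordinate is 0.
#' @return A list with class `"nm_options"`.
#' @export
nm_options <- function(reflection = 1, expansion = 2, contraction = 0.5,
                       shrink = 0.5, tol_x = 1e-4, tol_f = 1e-4,
                       max_evaluations = Inf, simplex_scale = 0.05,
                       zero_step = 0.00025) {
  stopifnot(reflection > 0, expansion > 1, contraction > 0, contraction < 1,
            shrink > 0, shrink < 1, tol_x >= 0, tol_f >= 0,
            max_evaluations >= 1)
  structure(list(reflection = reflection, expansion = expansion,
                 contraction = contraction, shrink = shrink,
                 tol_x = tol_x, tol_f = tol_f,
                 max_evaluations = max_evaluations,
                 simplex_scale = simplex_scale, zero_step = zero_step),
            class = "nm_options")
}

#' Budget-constrained Nelder-Mead simplex minimisation
#'
#' A derivative-free simplex search (reflect / expand / contract / shrink)
#' for noisy black-box objectives, with exact evaluation accounting: every
#' objective call is counted, the search stops the moment the budget is
#' exhausted, and the returned solution is the best vertex *ever
#' evaluated* (not merely the best in the final simplex — important when a
#' budget interrupts an iteration).  Non-finite objective values during
#' the search are treated as `+Inf` so the corresponding vertex is
#' rejected; a non-finite value at the start point is an error.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param x0 numeric start vector; the objective must be finite here.
#' @param opts an [nm_options()].
#' @return A `calibration_result`: list with `par`, `value`,
#'   `evaluations`, `trajectory` (best-so-far loss after each evaluation;
#'   non-increasing), `converged` (both tolerances met within budget).
#' @examples
#' r <- nelder_mead(function(x) sum((x - c(3, -2))^2), c(0, 0),
#'                  nm_options(max_evaluations = 200))
#' r$par
#' @export
nelder_mead <- function(objective, x0, opts = nm_options()) {
  stopifnot(is.numeric(x0), length(x0) >= 1)
  n <- length(x0)
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$traj <- numeric(0)
  env$best_f <- Inf
  env$best_x <- x0
  budget_cond <- structure(class = c("nm_budget", "condition"),
                           list(message = "budget exhausted", call = NULL))
  ev <- function(x) {
    if (env$count >= opts$max_evaluations) stop(budget_cond)
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1L) {
      stop("objective must return a single number", call. = FALSE)
    }
    if (!is.finite(f)) f <- Inf
    env$count <- env$count + 1L
    if (f < env$best_f) { env$best_f <- f; env$best_x <- x }
    env$traj[env$count] <- env$best_f
    f
  }

  converged <- FALSE
  res <- tryCatch({
    f0 <- ev(x0)
    if (!is.finite(f0)) {
      stop("objective is not finite at the start point", call. = FALSE)
    }
    V <- matrix(rep(x0, n + 1), nrow = n)
    for (j in seq_len(n)) {
      step <- if (x0[j] != 0) opts$simplex_scale * x0[j] else opts$zero_step
      V[j, j + 1] <- x0[j] + step
    }
    fv <- c(f0, vapply(seq_len(n), function(j) ev(V[, j + 1]), numeric(1)))

    repeat {
      ord <- order(fv)          # stable: equal values keep lowest index
      V <- V[, ord, drop = FALSE]
      fv <- fv[ord]
      spread_x <- max(abs(V[, -1, drop = FALSE] - V[, 1]))
      spread_f <- max(abs(fv[-1] - fv[1]))
      if (spread_x <= opts$tol_x && spread_f <= opts$tol_f) {
        converged <- TRUE
        break
      }
      centroid <- rowMeans(V[, -(n + 1), drop = FALSE])
      xr <- centroid + opts$reflection * (centroid - V[, n + 1])
      fr <- ev(xr)
      if (fr < fv[1]) {
        xe <- centroid + opts$expansion * (xr - centroid)
        fe <- ev(xe)
        if (fe < fr) { V[, n + 1] <- xe; fv[n + 1] <- fe }
        else         { V[, n + 1] <- xr; fv[n + 1] <- fr }
      } else if (fr < fv[n]) {
        V[, n + 1] <- xr; fv[n + 1] <- fr
      } else {
        do_shrink <- FALSE
        if (fr < fv[n + 1]) {   # outside contraction
          xc <- centroid + opts$contraction * (xr - centroid)
          fc <- ev(xc)
          if (fc <= fr) { V[, n + 1] <- xc; fv[n + 1] <- fc }
          else do_shrink <- TRUE
        } else {                # inside contraction
          xc <- centroid - opts$contraction * (centroid - V[, n + 1])
          fc <- ev(xc)
          if (fc < fv[n + 1]) { V[, n + 1] <- xc; fv[n + 1] <- fc }
          else do_shrink <- TRUE
        }
        if (do_shrink) {
          for (j in 2:(n + 1)) {
            V[, j] <- V[, 1] + opts$shrink * (V[, j] - V[, 1])
            fv[j] <- ev(V[, j])
          }
        }
      }
    }
    NULL
  }, nm_budget = function(e) NULL)

  structure(list(par = env$best_x, value = env$best_f,
                 evaluations = env$count, trajectory = env$traj,
                 converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss %.6g after %d evaluations%s\n",
              x$value, x$evaluations,
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}
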