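#' Per-generation response to selection
#'
#' `response_general()` maps selection gradients to the per-generation
#' change in the three trait means:
#' \deqn{\Delta\bar z_S = \tfrac12 G_{SS}[\beta_{NS} +
#'   \delta_{AS}(\beta_{NA} - \beta_{SA})] + \tfrac12 G_{SB}\beta_{NB}}
#' \deqn{\Delta\bar z_B = \tfrac12 G_{BB}\beta_{NB} +
#'   \tfrac12 G_{SB}[\beta_{NS} + \delta_{AS}(\beta_{NA} - \beta_{SA})]}
#' \deqn{\Delta\bar z_A = \tfrac12 G_{AA}\beta_{NA}}
#' The one-half multiplier arises because selection acts only on males
#' (dams are unselected). The responsiveness `deltaAS` routes both the
#' nonsocial and the social aggression gradients into signal (and, through
#' the honesty covariance `GSB`, body-size) evolution; setting `deltaAS = 0`
#' recovers the standard univariate response.
#'
#' `response_mechanistic()` substitutes the analytic gradients, giving the
#' closed form
#' \deqn{\Delta\bar z_S = \tfrac12 G_{SS}[\delta_{AS}(2 b_A + c_B \bar z_B)
#'   - c_S(\bar z_S - \theta_S)]}
#' with \eqn{\Delta\bar z_B = (G_{SB}/G_{SS})\,\Delta\bar z_S} and
#' \eqn{\Delta\bar z_A = \tfrac12 G_{AA}(b_A - c_A \bar z_A)}.
#' The two routes are algebraically identical.
#'
#' @param state A [population_state()].
#' @param gradients A [selection_gradients()] object.
#' @param G A [genetic_architecture()].
#' @param deltaAS Responsiveness of aggression to the signal difference.
#' @return Named numeric vector `c(dS, dB, dA)`.
#' @examples
#' p <- contest_params()
#' G <- genetic_architecture(GSB = 0.8)
#' s <- population_state(0, 0, 0)
#' response_mechanistic(s, p, G) # dS = 0.08, dB = 0.064, dA = 0.1
#' @export
response_general <- function(state, gradients, G, deltaAS) {
  stopifnot(inherits(gradients, "selection_gradients"),
            inherits(G, "genetic_architecture"))
  bN <- gradients$betaN
  bS <- gradients$betaS
  # shared bracket so that dB/dS = GSB/GSS holds exactly in floating point
  k <- bN[["S"]] + deltaAS * (bN[["A"]] - bS[["A"]])
  c(dS = 0.5 * G$GSS * k + 0.5 * G$GSB * bN[["B"]],
    dB = 0.5 * G$GBB * bN[["B"]] + 0.5 * G$GSB * k,
    dA = 0.5 * G$GAA * bN[["A"]])
}

#' @rdname response_general
#' @param params A [contest_params()] object.
#' @export
response_mechanistic <- function(state, params, G) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  k <- params$deltaAS * (2 * params$bA + params$cB * state$meanB) -
    params$cS * (state$meanS - params$thetaS)
  c(dS = 0.5 * G$GSS * k,
    dB = 0.5 * G$GSB * k,
    dA = 0.5 * G$GAA * (params$bA - params$cA * state$meanA))
}

#' Deterministic trajectory of trait means across generations
#'
#' Iterates the mechanistic response recursion with discrete, non-overlapping
#' generations and additive updates (\eqn{\bar z \leftarrow \bar z +
#' \Delta\bar z}), holding the genetic architecture and all fitness
#' coefficients constant. Iteration stops early when every per-generation
#' change falls below `tol` (`"converged"`), when any mean exceeds
#' `divergence_bound` in absolute value (`"diverged"`, the numerical
#' signature of a runaway), or otherwise after `max_generations`
#' (`"max_generations"`).
#'
#' @param initial A [population_state()] with the starting means.
#' @param params A [contest_params()] object.
#' @param G A [genetic_architecture()].
#' @param max_generations Maximum number of generations to iterate (>= 1).
#' @param tol Convergence tolerance on every per-generation change.
#' @param divergence_bound Absolute bound on any trait mean beyond which the
#'   trajectory is flagged as diverged.
#' @return A tibble of class `contest_trajectory` with one row per
#'   generation: `generation`, `mean_signal`, `mean_body`,
#'   `mean_aggression`, the per-generation changes `dS`, `dB`, `dA` (the
#'   change applied from this row to the next; `NA` on the final row if
#'   iteration stopped there), and the six selection gradients evaluated at
#'   the row's state. The termination flag is in `attr(x, "termination")`.
#' @examples
#' traj <- simulate_trajectory(population_state(0, 0, 0),
#'                             contest_params(),
#'                             genetic_architecture(GSB = 0.4))
#' attr(traj, "termination")
#' tail(traj$mean_aggression, 1) # bA / cA = 4
#' @export
simulate_trajectory <- function(initial, params, G,
                                max_generations = 10000,
                                tol = 1e-10,
                                divergence_bound = 1e6) {
  stopifnot(inherits(initial, "population_state"),
            inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  if (max_generations < 1) stop("max_generations must be >= 1", call. = FALSE)

  n_alloc <- max_generations + 1
  means <- matrix(NA_real_, n_alloc, 3,
                  dimnames = list(NULL, c("S", "B", "A")))
  deltas <- matrix(NA_real_, n_alloc, 3,
                   dimnames = list(NULL, c("dS", "dB", "dA")))
  grads <- matrix(NA_real_, n_alloc, 6)
  colnames(grads) <- c("betaNS", "betaNB", "betaNA",
                       "betaSS", "betaSB", "betaSA")

  z <- c(S = initial$meanS, B = initial$meanB, A = initial$meanA)
  termination <- "max_generations"
  t_final <- max_generations
  for (t in 0:max_generations) {
    if (!all(is.finite(z))) {
      stop("non-finite trait mean at generation ", t, call. = FALSE)
    }
    st <- population_state(z[["S"]], z[["B"]], z[["A"]], generation = t)
    means[t + 1, ] <- z
    grads[t + 1, ] <- gradients_vector(selection_gradients(params, st))
    if (any(abs(z) > divergence_bound)) {
      termination <- "diverged"
      t_final <- t
      break
    }
    if (t == max_generations) {
      t_final <- t
      break
    }
    d <- response_mechanistic(st, params, G)
    deltas[t + 1, ] <- d
    if (all(abs(d) < tol)) {
      termination <- "converged"
      t_final <- t
      break
    }
    z <- z + d
  }

  idx <- seq_len(t_final + 1)
  out <- tibble::tibble(
    generation = idx - 1L,
    mean_signal = means[idx, "S"],
    mean_body = means[idx, "B"],
    mean_aggression = means[idx, "A"],
    dS = deltas[idx, "dS"],
    dB = deltas[idx, "dB"],
    dA = deltas[idx, "dA"]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(grads[idx, , drop = FALSE]))
  class(out) <- c("contest_trajectory", class(out))
  attr(out, "termination") <- termination
  attr(out, "params") <- params
  attr(out, "G") <- G
  out
}

#' @export
#' @rdname simulate_trajectory
#' @param x A `contest_trajectory`.
#' @param ... Unused.
glance.contest_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    generations = x$generation[n],
    termination = attr(x, "termination"),
    final_signal = x$mean_signal[n],
    final_body = x$mean_body[n],
    final_aggression = x$mean_aggression[n]
  )
}

#' Write / read a trajectory as CSV
#'
#' Plain-CSV serialisation of a [simulate_trajectory()] result (columns:
#' generation, means, per-generation changes, six gradients).
#'
#' @param trajectory A `contest_trajectory` tibble.
#' @param path Output CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(as.data.frame(trajectory), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
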