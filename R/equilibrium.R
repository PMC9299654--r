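#' Equilibrium mean aggression
#'
#' Aggression always equilibrates where the marginal benefit of escalation
#' equals its marginal cost: \eqn{\hat{\bar z}_A = b_A / c_A}.
#'
#' @param params A [contest_params()] object with `cA > 0`.
#' @return The equilibrium mean aggression (trait units).
#' @examples
#' aggression_equilibrium(contest_params(bA = 0.2, cA = 0.05)) # 4
#' @export
aggression_equilibrium <- function(params) {
  stopifnot(inherits(params, "contest_params"))
  if (params$cA <= 0) {
    stop("cA must be > 0: without a cost of mutual aggression there is no ",
         "finite aggression equilibrium", call. = FALSE)
  }
  params$bA / params$cA
}

#' Line of equilibria for signal and body size
#'
#' Signal and body-size evolution are completely intertwined
#' (\eqn{\Delta\bar z_B = (G_{SB}/G_{SS})\Delta\bar z_S}), so their joint
#' equilibria form a line rather than a point. Expressed as mean signal
#' against mean body size:
#' \deqn{\hat{\bar z}_S = \theta_S + \frac{2\,\delta_{AS} b_A}{c_S} +
#'       \frac{\delta_{AS} c_B}{c_S}\,\hat{\bar z}_B.}
#' The slope \eqn{\delta_{AS} c_B / c_S} is the predicted evolutionary
#' allometry of signal on body size across populations; a slope above one
#' (positive allometry) needs signal-driven social costs to outweigh
#' natural selection. `equilibrium_line_inverse()` returns the same line
#' solved for body size as a function of signal; it is derived by inverting
#' the line above, and equals the printed closed form
#' \eqn{\hat{\bar z}_B = \frac{c_S}{\delta_{AS} c_B}(\hat{\bar z}_S -
#' \theta_S) - \frac{2 b_A}{c_B}}.
#'
#' @param params A [contest_params()] object with `cS > 0` (and, for the
#'   inverse, `deltaAS * cB != 0`).
#' @return A named numeric vector `c(intercept, slope)`.
#' @examples
#' equilibrium_line(contest_params()) # intercept 3.2, slope 1.6
#' @export
equilibrium_line <- function(params) {
  stopifnot(inherits(params, "contest_params"))
  if (params$cS <= 0) {
    stop("cS must be > 0: with no naturally selected optimum the line of ",
         "equilibria is undefined (pure runaway whenever deltaAS * cB > 0)",
         call. = FALSE)
  }
  c(intercept = params$thetaS + 2 * params$deltaAS * params$bA / params$cS,
    slope = params$deltaAS * params$cB / params$cS)
}

#' @rdname equilibrium_line
#' @export
equilibrium_line_inverse <- function(params) {
  ln <- equilibrium_line(params)
  if (ln[["slope"]] == 0) {
    stop("deltaAS * cB = 0: the line is vertical in (body, signal) space ",
         "and cannot be expressed as body size on signal", call. = FALSE)
  }
  c(intercept = -ln[["intercept"]] / ln[["slope"]],
    slope = 1 / ln[["slope"]])
}

#' Runaway condition for signal-body coevolution
#'
#' The line of equilibria is unstable — signal and body size run away
#' together — exactly when honesty-weighted social selection beats natural
#' selection on the signal:
#' \deqn{\frac{G_{SB}}{G_{SS}}\,\delta_{AS}\,c_B > c_S.}
#' The margin is the left side minus the right side. Within `dead_band` of
#' zero the case is reported as `"marginal"` rather than classified: the
#' knife edge is not numerically decidable.
#'
#' @param params A [contest_params()] object.
#' @param G A [genetic_architecture()] with `GSS > 0`.
#' @param dead_band Half-width of the unclassified band around margin zero.
#' @return A list with `runaway` (logical, `NA` when marginal), `margin`
#'   and `classification` (`"runaway"`, `"stable"` or `"marginal"`).
#' @examples
#' p <- contest_params()
#' runaway_condition(p, genetic_architecture(GSB = 0.4))$margin # -0.018
#' runaway_condition(p, genetic_architecture(GSB = 0.8))$margin # +0.014
#' @export
runaway_condition <- function(params, G, dead_band = 1e-9) {
  stopifnot(inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  if (G$GSS <= 0) {
    stop("GSS must be > 0 to evaluate the runaway condition", call. = FALSE)
  }
  # grouped as covariance-ratio times sexual-selection force, mirroring the
  # female-choice comparator bit for bit
  margin <- (G$GSB / G$GSS) * (params$deltaAS * params$cB) - params$cS
  if (abs(margin) < dead_band) {
    list(runaway = NA, margin = margin, classification = "marginal")
  } else {
    list(runaway = margin > 0, margin = margin,
         classification = if (margin > 0) "runaway" else "stable")
  }
}

#' Jacobian eigenvalues of the signal/body update map
#'
#' The aggression recursion is autonomous and contracting whenever
#' \eqn{0 < \tfrac12 G_{AA} c_A < 2}, so stability of the full system is
#' decided by the two-dimensional (signal, body) subsystem. Its update map
#' has Jacobian (of the per-generation changes with respect to the means)
#' \deqn{\tfrac12 \begin{pmatrix} -G_{SS} c_S & G_{SS}\delta_{AS}c_B \\
#'       -G_{SB} c_S & G_{SB}\delta_{AS}c_B \end{pmatrix},}
#' a rank-one matrix: one eigenvalue is always 0 (the line of equilibria is
#' neutral along itself) and the other is
#' \eqn{\tfrac12 (G_{SB}\delta_{AS}c_B - G_{SS} c_S)}, whose sign agrees
#' with the runaway margin.
#'
#' @inheritParams runaway_condition
#' @return Numeric vector of the two eigenvalues, nonzero one first.
#' @examples
#' jacobian_eigenvalues(contest_params(), genetic_architecture(GSB = 0.8))
#' @export
jacobian_eigenvalues <- function(params, G) {
  stopifnot(inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  lambda <- 0.5 * (G$GSB * params$deltaAS * params$cB - G$GSS * params$cS)
  c(lambda, 0)
}

#' Full equilibrium and stability report
#'
#' Combines the aggression equilibrium, the line of equilibria, the
#' Jacobian eigenvalues and the runaway classification into one object,
#' serialisable as JSON.
#'
#' @inheritParams runaway_condition
#' @return An object of class `equilibrium_report`: a list with fields
#'   `zA_hat`, `line_intercept`, `line_slope`, `eigenvalues`, `runaway`,
#'   `margin` and `classification`.
#' @examples
#' equilibrium_report(contest_params(), genetic_architecture(GSB = 0.4))
#' @export
equilibrium_report <- function(params, G, dead_band = 1e-9) {
  ln <- equilibrium_line(params)
  rc <- runaway_condition(params, G, dead_band = dead_band)
  structure(list(
    zA_hat = aggression_equilibrium(params),
    line_intercept = ln[["intercept"]],
    line_slope = ln[["slope"]],
    eigenvalues = jacobian_eigenvalues(params, G),
    runaway = rc$runaway,
    margin = rc$margin,
    classification = rc$classification
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n")
  cat(sprintf("  aggression equilibrium: %g\n", x$zA_hat))
  cat(sprintf("  line of equilibria: signal = %g + %g * body\n",
              x$line_intercept, x$line_slope))
  cat(sprintf("  eigenvalues: %g, %g\n", x$eigenvalues[1], x$eigenvalues[2]))
  cat(sprintf("  classification: %s (margin %g)\n", x$classification,
              x$margin))
  invisible(x)
}

#' @rdname equilibrium_report
#' @param report An `equilibrium_report`.
#' @param path Output JSON path.
#' @export
write_equilibrium_report <- function(report, path) {
  stopifnot(inherits(report, "equilibrium_report"))
  out <- unclass(report)
  out$mechanism <- "male-male competition"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
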