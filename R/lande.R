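#' Parameters of the female-choice (Fisher-Lande) comparator
#'
#' Static parameters of Lande's relative-preference model of runaway
#' sexual selection by female choice, used for side-by-side comparison
#' with the male-male competition mechanism.
#'
#' @param theta Naturally selected optimum of the male trait.
#' @param bSS Strength of sexual selection generated by female preference.
#' @param cNS Strength of natural selection on the male trait.
#' @param Gmm Additive-genetic variance of the male trait (> 0).
#' @param Gmf Additive-genetic covariance between male trait and female
#'   preference (arises from linkage disequilibrium under assortative
#'   mating).
#' @return An object of class `lande_params`.
#' @examples
#' lande_params(theta = 0, bSS = 0.2, cNS = 0.05, Gmm = 1, Gmf = 0.4)
#' @export
lande_params <- function(theta = 0, bSS = 0.2, cNS = 0.05,
                         Gmm = 1, Gmf = 0) {
  vals <- c(theta = theta, bSS = bSS, cNS = cNS, Gmm = Gmm, Gmf = Gmf)
  if (!all(is.finite(vals))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  if (Gmm <= 0) stop("Gmm must be > 0", call. = FALSE)
  structure(as.list(vals), class = "lande_params")
}

#' Lande's line of equilibria for trait and preference
#'
#' \deqn{\hat z = \theta + \frac{b_{SS}}{c_{NS}} \hat y} — the male trait
#' equilibrium as a function of mean female preference. Under the mapping
#' `bSS <-> deltaAS * cB`, `cNS <-> cS`, the slope equals the
#' male-competition [equilibrium_line()] slope: in contests, the "force of
#' sexual selection" is supplied by the threat of the opponent routed
#' through behavioural responsiveness rather than by female preference.
#'
#' @param p A [lande_params()] object with `cNS > 0`.
#' @return Named numeric vector `c(intercept, slope)`.
#' @examples
#' lande_line(lande_params(bSS = 0.2, cNS = 0.05)) # slope 4
#' @export
lande_line <- function(p) {
  stopifnot(inherits(p, "lande_params"))
  if (p$cNS <= 0) {
    stop("cNS must be > 0: without natural selection the line of ",
         "equilibria is undefined", call. = FALSE)
  }
  c(intercept = p$theta, slope = p$bSS / p$cNS)
}

#' Lande's runaway condition
#'
#' The female-choice line of equilibria is unstable when
#' \deqn{\frac{G_{mf}}{G_{mm}} b_{SS} > c_{NS}.}
#' Under the mapping `Gmf <-> GSB`, `Gmm <-> GSS`, `bSS <-> deltaAS * cB`,
#' `cNS <-> cS`, the margin equals the male-competition
#' [runaway_condition()] margin exactly: both runaways are driven by a
#' genetic covariance — linkage disequilibrium between trait and preference
#' in mate choice, pleiotropic signal honesty in male contests.
#'
#' @param p A [lande_params()] object.
#' @param dead_band Half-width of the unclassified band around margin zero.
#' @return A list with `runaway`, `margin` and `classification`, as in
#'   [runaway_condition()].
#' @examples
#' lande_runaway(lande_params(bSS = 0.08, cNS = 0.05, Gmf = 0.8))
#' @export
lande_runaway <- function(p, dead_band = 1e-9) {
  stopifnot(inherits(p, "lande_params"))
  margin <- (p$Gmf / p$Gmm) * p$bSS - p$cNS
  if (abs(margin) < dead_band) {
    list(runaway = NA, margin = margin, classification = "marginal")
  } else {
    list(runaway = margin > 0, margin = margin,
         classification = if (margin > 0) "runaway" else "stable")
  }
}

#' Map male-competition parameters onto the Lande comparator
#'
#' Applies the documented structural mapping (`Gmf <- GSB`, `Gmm <- GSS`,
#' `bSS <- deltaAS * cB`, `cNS <- cS`, `theta <- thetaS`) so the two
#' mechanisms can be classified side by side.
#'
#' @param params A [contest_params()] object.
#' @param G A [genetic_architecture()].
#' @return A [lande_params()] object.
#' @examples
#' as_lande_params(contest_params(), genetic_architecture(GSB = 0.8))
#' @export
as_lande_params <- function(params, G) {
  stopifnot(inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  lande_params(theta = params$thetaS,
               bSS = params$deltaAS * params$cB,
               cNS = params$cS,
               Gmm = G$GSS,
               Gmf = G$GSB)
}

#' @rdname lande_runaway
#' @param path Output JSON path.
#' @export
write_lande_report <- function(p, path, dead_band = 1e-9) {
  ln <- lande_line(p)
  rc <- lande_runaway(p, dead_band = dead_band)
  out <- list(zA_hat = NULL,
              line_intercept = ln[["intercept"]],
              line_slope = ln[["slope"]],
              eigenvalues = NULL,
              runaway = rc$runaway,
              margin = rc$margin,
              classification = rc$classification,
              mechanism = "female choice (Lande)")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
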