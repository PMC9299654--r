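#' Express context-dependent aggression within a dyad
#'
#' Aggression is socially contingent: a male's realised aggression is his
#' intrinsic (genetic plus environmental) aggression shifted by `deltaAS`
#' times the difference between his own signal and his opponent's. Because
#' the shift depends on the opponent's heritable signal, it is an indirect
#' genetic effect. The `deltaAS` contributions of the two members of a dyad
#' are equal in magnitude and opposite in sign.
#'
#' @param focal,opponent Data frames (or single rows) of males with columns
#'   `aA`, `eA`, `zS` for the focal and `zS` for the opponent. Rows are
#'   matched positionally (row i of `focal` fights row i of `opponent`).
#' @param params A [contest_params()] object (only `deltaAS` is used).
#' @return Numeric vector of realised aggression phenotypes, one per dyad
#'   row. Signal and body size are fixed before the contest and are never
#'   altered by it; only aggression is context dependent.
#' @examples
#' p <- contest_params(deltaAS = 0.4)
#' focal <- data.frame(aA = 1, eA = 0, zS = 3)
#' rival <- data.frame(zS = 1)
#' express_aggression(focal, rival, p) # 1 + 0.4 * (3 - 1) = 1.8
#' @export
express_aggression <- function(focal, opponent, params) {
  stopifnot(inherits(params, "contest_params"))
  focal$aA + focal$eA + params$deltaAS * (focal$zS - opponent$zS)
}

#' Contest fitness of a focal male
#'
#' Deterministic relative fitness of a focal male in a pairwise duel:
#' \deqn{w = w_0 + b_A (z_A - z_A') - c_A z_A z_A' - c_B z_A' z_B'
#'           - c_S (\bar z_S - \theta_S) z_S}
#' The benefit term and the mutual-aggression cost derive from the hawk-dove
#' game: out-aggressing a rival wins access to females (`bA`), while mutual
#' escalation is costly (`cA`). The "threat of the opponent" cost (`cB`)
#' scales with the opponent's aggression times his body size, and stabilising
#' natural selection (`cS`) penalises signals in proportion to how far the
#' population mean signal sits from its optimum. The benefit terms of the
#' two dyad members cancel: summed over a dyad, fitness is invariant to
#' `bA`. Noise belongs to the individual-based simulator, not here.
#'
#' @param focal Data frame rows with columns `zS` and `zA` (aggression
#'   already expressed within this dyad via [express_aggression()]).
#' @param opponent Data frame rows with columns `zA` and `zB`.
#' @param params A [contest_params()] object.
#' @param meanS Current population mean signal (the stabilising-selection
#'   term is frequency dependent through it).
#' @return Numeric vector of relative fitness values; may be negative far
#'   from the origin (the surface is a local quadratic model).
#' @examples
#' p <- contest_params(bA = 0.2, cA = 0, cB = 0, cS = 0, w0 = 1)
#' contest_fitness(data.frame(zS = 0, zA = 2),
#'                 data.frame(zB = 0, zA = 1), p, meanS = 0) # 1.2
#' @export
contest_fitness <- function(focal, opponent, params, meanS) {
  stopifnot(inherits(params, "contest_params"))
  params$w0 +
    params$bA * (focal$zA - opponent$zA) -
    params$cA * focal$zA * opponent$zA -
    params$cB * opponent$zA * opponent$zB -
    params$cS * (meanS - params$thetaS) * focal$zS
}

#' Analytic nonsocial and social selection gradients
#'
#' Partial derivatives of the contest fitness surface with respect to the
#' focal male's own traits (nonsocial gradients, `betaN`) and his opponent's
#' traits (social gradients, `betaS`), evaluated at the population mean:
#' \deqn{\beta_{NS} = -c_S(\bar z_S - \theta_S), \quad \beta_{NB} = 0, \quad
#'       \beta_{NA} = b_A - c_A \bar z_A}
#' \deqn{\beta_{SS} = 0, \quad \beta_{SB} = -c_B \bar z_A, \quad
#'       \beta_{SA} = -(b_A + c_A \bar z_A + c_B \bar z_B)}
#' `betaNB` and `betaSS` vanish identically: body size is not under direct
#' nonsocial selection, and a rival's signal imposes no direct fitness cost
#' — the signal matters only through the behaviour it provokes.
#'
#' @param params A [contest_params()] object.
#' @param state A [population_state()] with the current trait means.
#' @return An object of class `selection_gradients`: a list with named
#'   numeric vectors `betaN` and `betaS` (names `"S"`, `"B"`, `"A"`).
#'   Use [tidy()] for a tibble view.
#' @examples
#' p <- contest_params(bA = 0.2, cA = 0.05, cB = 0.2, cS = 0.05)
#' selection_gradients(p, population_state(0, 10, 4))
#' @export
selection_gradients <- function(params, state) {
  stopifnot(inherits(params, "contest_params"),
            inherits(state, "population_state"))
  betaN <- c(S = -params$cS * (state$meanS - params$thetaS),
             B = 0,
             A = params$bA - params$cA * state$meanA)
  betaS <- c(S = 0,
             B = -params$cB * state$meanA,
             A = -(params$bA + params$cA * state$meanA +
                     params$cB * state$meanB))
  structure(list(betaN = betaN, betaS = betaS), class = "selection_gradients")
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat("<selection_gradients>\n")
  cat(sprintf("  nonsocial: betaNS=%g betaNB=%g betaNA=%g\n",
              x$betaN[["S"]], x$betaN[["B"]], x$betaN[["A"]]))
  cat(sprintf("  social:    betaSS=%g betaSB=%g betaSA=%g\n",
              x$betaS[["S"]], x$betaS[["B"]], x$betaS[["A"]]))
  invisible(x)
}

#' @export
#' @rdname selection_gradients
#' @param x A `selection_gradients` object.
#' @param ... Unused.
tidy.selection_gradients <- function(x, ...) {
  tibble::tibble(
    gradient = c("betaNS", "betaNB", "betaNA", "betaSS", "betaSB", "betaSA"),
    pathway = rep(c("nonsocial", "social"), each = 3),
    trait = rep(c("signal", "body", "aggression"), 2),
    value = c(unname(x$betaN), unname(x$betaS))
  )
}

# Gradients as a flat named vector in trajectory-column order.
gradients_vector <- function(g) {
  c(betaNS = g$betaN[["S"]], betaNB = g$betaN[["B"]], betaNA = g$betaN[["A"]],
    betaSS = g$betaS[["S"]], betaSB = g$betaS[["B"]], betaSA = g$betaS[["A"]])
}
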