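# Shared parameterisations: the two reference regimes (weak vs strong signal honesty) (weak vs strong
# signal honesty) and small helpers used across test files.

base_params <- function(bA = 0.2, cA = 0.05, cB = 0.2, cS = 0.05,
                        thetaS = 0, deltaAS = 0.4, w0 = 1) {
  contest_params(bA = bA, cA = cA, cB = cB, cS = cS, thetaS = thetaS,
                 deltaAS = deltaAS, w0 = w0)
}

weak_honesty_G <- function() genetic_architecture(GSS = 1, GBB = 1, GAA = 1,
                                           GSB = 0.4)
strong_honesty_G <- function() genetic_architecture(GSS = 1, GBB = 1, GAA = 1,
                                           GSB = 0.8)

origin_state <- function() population_state(0, 0, 0)

# A male data-frame row with explicit phenotype slots, for the pure
# model-core functions.
male_row <- function(aA = 0, eA = 0, zS = 0, zB = 0, zA = NA_real_) {
  data.frame(aA = aA, eA = eA, zS = zS, zB = zB, zA = zA)
}

# Independent oracle: central-difference partial derivatives of the contest
# fitness surface with respect to the six phenotype slots, evaluated at the
# population mean. Uses only contest_fitness() arithmetic, never the
# analytic gradient formulas.
numeric_gradients <- function(params, state, h = 1e-5) {
  at <- c(zS = state$meanS, zB = state$meanB, zA = state$meanA,
          zS. = state$meanS, zB. = state$meanB, zA. = state$meanA)
  f <- function(v) {
    focal <- data.frame(zS = v[["zS"]], zB = v[["zB"]], zA = v[["zA"]])
    opp <- data.frame(zS = v[["zS."]], zB = v[["zB."]], zA = v[["zA."]])
    contest_fitness(focal, opp, params, meanS = state$meanS)
  }
  grad <- vapply(names(at), function(nm) {
    up <- at; up[[nm]] <- up[[nm]] + h
    dn <- at; dn[[nm]] <- dn[[nm]] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
  list(betaN = c(S = grad[["zS"]], B = grad[["zB"]], A = grad[["zA"]]),
       betaS = c(S = grad[["zS."]], B = grad[["zB."]], A = grad[["zA."]]))
}

random_params <- function() {
  contest_params(bA = runif(1, 0, 0.5), cA = runif(1, 0.01, 0.2),
                 cB = runif(1, 0, 0.4), cS = runif(1, 0.01, 0.2),
                 thetaS = runif(1, -2, 2), deltaAS = runif(1, -1, 1),
                 w0 = runif(1, 0.5, 2))
}

random_state <- function() {
  population_state(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5))
}

random_G <- function() {
  GSS <- runif(1, 0.2, 2); GBB <- runif(1, 0.2, 2)
  genetic_architecture(GSS = GSS, GBB = GBB, GAA = runif(1, 0.2, 2),
                       GSB = runif(1, -0.9, 0.9) * sqrt(GSS * GBB))
}
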