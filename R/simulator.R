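# Substream seeds: one user-facing integer seed expands deterministically to
# independent seeds for sampling, pairing, fitness noise and reproduction, so
# each phase is separately reproducible. Derivation: Lehmer step modulo the
# Mersenne prime 2^31 - 1, offset by the phase index.
substream_seed <- function(seed, phase) {
  phases <- c(sampling = 1, pairing = 2, noise = 3, reproduction = 4)
  if (!phase %in% names(phases)) stop("unknown seed phase: ", phase)
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + phases[[phase]]) %% m)
}

#' Sample a male population
#'
#' Draws `n` males from the quantitative-genetic model: breeding values from
#' the trivariate normal with means at the current population state and
#' covariance matrix [G_matrix()] (aggression genetically uncorrelated with
#' signal and body size), independent environmental deviations from
#' [E_matrix()], and phenotypes `zS = aS + eS`, `zB = aB + eB`. Intrinsic
#' aggression `aA + eA` is sampled here; the realised aggression phenotype
#' is context dependent and only expressed within a dyad.
#'
#' @param n Number of males; must be even (pairwise duels) and >= 2.
#' @param state A [population_state()] giving the mean breeding values.
#' @param G A [genetic_architecture()].
#' @param seed Integer seed (expanded to an internal sampling substream).
#' @return A tibble with one row per male: `id`, breeding values `aS`, `aB`,
#'   `aA`, environmental deviations `eS`, `eB`, `eA`, and phenotypes `zS`,
#'   `zB`.
#' @examples
#' males <- sample_males(100, population_state(0, 0, 0),
#'                       genetic_architecture(GSB = 0.4), seed = 1)
#' @export
sample_males <- function(n, state, G, seed = 1L) {
  stopifnot(inherits(state, "population_state"),
            inherits(G, "genetic_architecture"))
  if (n < 2 || n %% 2 != 0) {
    stop("n must be even and >= 2 (males fight in pairwise duels)",
         call. = FALSE)
  }
  Gm <- G_matrix(G)
  Em <- E_matrix(G)
  ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("genetic covariance matrix is not positive semidefinite",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "sampling"))
  mu <- c(state$meanS, state$meanB, state$meanA)
  a <- MASS::mvrnorm(n, mu = mu, Sigma = Gm)
  e <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = Em)
  if (n == 1) { a <- matrix(a, 1); e <- matrix(e, 1) }
  tibble::tibble(
    id = seq_len(n),
    aS = a[, 1], aB = a[, 2], aA = a[, 3],
    eS = e[, 1], eB = e[, 2], eA = e[, 3],
    zS = a[, 1] + e[, 1],
    zB = a[, 2] + e[, 2]
  )
}

#' Calibrate the fitness intercept so mean contest fitness is one
#'
#' The contest fitness surface is a relative-fitness model with a free
#' intercept `w0`. Its expectation at a population state follows from
#' Gaussian moments of the generator:
#' \deqn{E[w] = w_0 - c_A(\bar z_A^2 - 2\delta_{AS}^2\sigma_S^2)
#'   - c_B(\bar z_A \bar z_B + \delta_{AS}(G_{SB}+E_{SB}))
#'   - c_S(\bar z_S - \theta_S)\bar z_S,}
#' with \eqn{\sigma_S^2 = G_{SS} + E_{SS}}. `calibrate_w0()` returns the
#' `w0` for which \eqn{E[w] = 1}, so that within-sample normalisation to
#' relative fitness is asymptotically a no-op and regression estimates of
#' the selection gradients are on the analytic scale. Far from the origin
#' the quadratic cost terms are large, and an uncalibrated intercept would
#' make mean fitness small or negative.
#'
#' @inheritParams sample_males
#' @param params A [contest_params()] object.
#' @return The calibrated intercept (scalar).
#' @examples
#' calibrate_w0(population_state(0, 10, 4), contest_params(),
#'              genetic_architecture(GSB = 0.4))
#' @export
calibrate_w0 <- function(state, params, G) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "contest_params"),
            inherits(G, "genetic_architecture"))
  sigmaS2 <- G$GSS + G$ESS
  E_zAzA <- state$meanA^2 - 2 * params$deltaAS^2 * sigmaS2
  E_zAzB <- state$meanA * state$meanB + params$deltaAS * (G$GSB + G$ESB)
  1 + params$cA * E_zAzA + params$cB * E_zAzB +
    params$cS * (state$meanS - params$thetaS) * state$meanS
}

#' Run one round of pairwise contests
#'
#' Males are paired by a random perfect matching (one duel per male). Each
#' dyad member expresses context-dependent aggression, receives the
#' deterministic contest fitness plus independent mean-zero Gaussian noise,
#' and the fitness column is normalised within-sample to relative fitness
#' (divided by its mean). Every male appears exactly once as focal and once
#' as opponent, so the table has one row per male and relabelling
#' focal/opponent within dyads leaves estimated quantities unchanged.
#'
#' @param males A tibble from [sample_males()].
#' @param params A [contest_params()] object.
#' @param seed Integer seed (pairing and noise substreams are derived from
#'   it).
#' @param meanS Population mean signal used by the stabilising-selection
#'   term; defaults to the sample mean of `zS`.
#' @param noise_var Variance of the fitness noise; default `0.01 * w0^2`.
#' @return A tibble of class `contest_table` with columns `focal_id`,
#'   `focal_zS`, `focal_zB`, `focal_zA`, `opp_zS`, `opp_zB`, `opp_zA`, `w`
#'   (relative fitness). Attributes: `params`, `n`, `seed`, `generation`,
#'   `truncation_count` (rows whose raw fitness was negative and would be
#'   truncated by reproduction).
#' @examples
#' males <- sample_males(200, population_state(0, 0, 0),
#'                       genetic_architecture(GSB = 0.4), seed = 1)
#' tab <- run_contests(males, contest_params(), seed = 1)
#' mean(tab$w) # exactly 1 by construction
#' @export
run_contests <- function(males, params, seed = 1L, meanS = NULL,
                         noise_var = NULL) {
  stopifnot(inherits(params, "contest_params"))
  n <- nrow(males)
  if (n %% 2 != 0) stop("male count must be even", call. = FALSE)
  if (is.null(meanS)) meanS <- mean(males$zS)
  if (is.null(noise_var)) noise_var <- 0.01 * params$w0^2

  set.seed(substream_seed(seed, "pairing"))
  perm <- sample.int(n)
  first <- perm[seq(1, n, by = 2)]
  second <- perm[seq(2, n, by = 2)]
  focal_idx <- c(first, second)
  opp_idx <- c(second, first)

  focal <- males[focal_idx, ]
  opp <- males[opp_idx, ]
  focal$zA <- express_aggression(focal, opp, params)
  opp$zA <- focal$zA[match(opp_idx, focal_idx)]

  w_raw <- contest_fitness(focal, opp, params, meanS = meanS)
  set.seed(substream_seed(seed, "noise"))
  if (noise_var > 0) w_raw <- w_raw + stats::rnorm(n, 0, sqrt(noise_var))
  w_bar <- mean(w_raw)
  if (w_bar <= 0) {
    stop("mean contest fitness is non-positive; increase w0 (see ",
         "calibrate_w0()) — the quadratic cost terms dominate at this state",
         call. = FALSE)
  }
  out <- tibble::tibble(
    focal_id = males$id[focal_idx],
    focal_zS = focal$zS, focal_zB = focal$zB, focal_zA = focal$zA,
    opp_zS = opp$zS, opp_zB = opp$zB, opp_zA = opp$zA,
    w = w_raw / w_bar
  )
  out <- out[order(out$focal_id), ]
  class(out) <- c("contest_table", class(out))
  attr(out, "params") <- params
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "generation") <- 0L
  attr(out, "truncation_count") <- sum(w_raw < 0)
  out
}

#' Generate a dyadic contest table at a given population state
#'
#' Convenience wrapper: sample a population, run one round of contests and
#' return the resulting table. By default the fitness intercept is
#' calibrated with [calibrate_w0()] so that expected fitness at the
#' generating state is 1; set `calibrate = FALSE` to use `params$w0` as is.
#'
#' @inheritParams sample_males
#' @inheritParams run_contests
#' @param calibrate Calibrate `w0` to the generating state (default TRUE).
#' @return A `contest_table` tibble (see [run_contests()]).
#' @examples
#' tab <- make_contest_table(1000, population_state(0, 0, 0),
#'                           contest_params(), genetic_architecture(GSB = 0.4),
#'                           seed = 7)
#' @export
make_contest_table <- function(n, state, params, G, seed = 1L,
                               calibrate = TRUE, noise_var = NULL) {
  if (calibrate) params$w0 <- calibrate_w0(state, params, G)
  males <- sample_males(n, state, G, seed = seed)
  tab <- run_contests(males, params, seed = seed, meanS = state$meanS,
                      noise_var = noise_var)
  attr(tab, "state") <- state
  tab
}

#' Population means of the next generation
#'
#' Maps realised contest fitness to reproduction: sires are drawn
#' multinomially with probability proportional to their (non-negative)
#' relative fitness, dams are unselected and carry the population mean
#' breeding value, and each offspring's expected breeding value is the
#' midparent \eqn{\tfrac12 a_{sire} + \tfrac12 \bar a}. This realises the
#' one-half multiplier of the male-only response to selection. Negative
#' relative fitness is truncated to zero and counted (the fitness surface
#' is a local model; far along a runaway the truncation count grows and
#' with it the truncation bias).
#'
#' @param table A `contest_table` from [run_contests()].
#' @param males The tibble of males that produced `table`.
#' @param state The [population_state()] that generated `males` (its
#'   generation index is advanced).
#' @param seed Integer seed (reproduction substream).
#' @return A [population_state()] for the next generation, with attributes
#'   `response` (named vector `dS`, `dB`, `dA` of change relative to the
#'   realised parental breeding-value means) and `truncation_count`.
#' @examples
#' st <- population_state(0, 0, 0)
#' G <- genetic_architecture(GSB = 0.4)
#' males <- sample_males(2000, st, G, seed = 2)
#' tab <- run_contests(males, contest_params(), seed = 2)
#' next_generation_means(tab, males, st, seed = 2)
#' @export
next_generation_means <- function(table, males, state, seed = 1L) {
  stopifnot(inherits(table, "contest_table"),
            inherits(state, "population_state"))
  n <- nrow(males)
  if (nrow(table) != n) {
    stop("contest table and male population do not correspond", call. = FALSE)
  }
  w <- table$w[match(males$id, table$focal_id)]
  w_pos <- pmax(w, 0)
  if (all(w_pos <= 0)) {
    stop("degenerate selection: all realised fitness values are <= 0",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "reproduction"))
  counts <- stats::rmultinom(1, size = n, prob = w_pos / sum(w_pos))[, 1]
  parent_mean <- c(S = mean(males$aS), B = mean(males$aB), A = mean(males$aA))
  sire_mean <- c(S = sum(counts * males$aS),
                 B = sum(counts * males$aB),
                 A = sum(counts * males$aA)) / n
  new_mean <- 0.5 * sire_mean + 0.5 * parent_mean
  out <- population_state(new_mean[["S"]], new_mean[["B"]], new_mean[["A"]],
                          generation = state$generation + 1L)
  attr(out, "response") <- stats::setNames(new_mean - parent_mean,
                                           c("dS", "dB", "dA"))
  attr(out, "truncation_count") <- sum(w < 0)
  out
}

#' Multi-generation individual-based simulation
#'
#' Chains [sample_males()], [run_contests()] and [next_generation_means()]
#' over generations, regenerating the population from the updated means each
#' generation (the genetic architecture is held constant). With `replicates
#' > 1`, independent replicate runs share the parameterisation but use
#' distinct derived seeds.
#'
#' @inheritParams sample_males
#' @param params A [contest_params()] object.
#' @param generations Number of generations to simulate.
#' @param initial Initial [population_state()].
#' @param replicates Number of independent replicate runs.
#' @param calibrate Recalibrate `w0` to the current state each generation
#'   (default TRUE; keeps mean fitness near 1 as means evolve).
#' @return A tibble with columns `replicate`, `generation`, `mean_signal`,
#'   `mean_body`, `mean_aggression`, `truncated` (count of
#'   negative-fitness males).
#' @examples
#' sim <- simulate_contests(n = 500, generations = 3, params = contest_params(),
#'                          G = genetic_architecture(GSB = 0.4),
#'                          initial = population_state(0, 0, 0), seed = 3)
#' @export
simulate_contests <- function(n, generations, params, G,
                              initial = population_state(0, 0, 0),
                              replicates = 1, seed = 1L, calibrate = TRUE) {
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  one_rep <- function(rep_id) {
    st <- initial
    rows <- vector("list", generations + 1)
    rows[[1]] <- tibble::tibble(replicate = rep_id, generation = 0L,
                                mean_signal = st$meanS, mean_body = st$meanB,
                                mean_aggression = st$meanA, truncated = 0L)
    for (g in seq_len(generations)) {
      gen_seed <- substream_seed(seed + 7919L * rep_id, "sampling") + g
      p <- params
      if (calibrate) p$w0 <- calibrate_w0(st, params, G)
      males <- sample_males(n, st, G, seed = gen_seed)
      tab <- run_contests(males, p, seed = gen_seed, meanS = st$meanS)
      st <- next_generation_means(tab, males, st, seed = gen_seed)
      rows[[g + 1]] <- tibble::tibble(
        replicate = rep_id, generation = st$generation,
        mean_signal = st$meanS, mean_body = st$meanB,
        mean_aggression = st$meanA,
        truncated = attr(st, "truncation_count")
      )
    }
    dplyr::bind_rows(rows)
  }
  purrr::map_dfr(seq_len(replicates), one_rep)
}

#' Write / read a contest table as CSV with a JSON sidecar
#'
#' The CSV carries the dyadic records (`focal_zS`, `focal_zB`, `focal_zA`,
#' `opp_zS`, `opp_zB`, `opp_zA`, `w`); run metadata (parameters, n, seed,
#' generation, truncation count) goes to `<path>.meta.json`.
#'
#' @param table A `contest_table`.
#' @param path Output CSV path.
#' @return `write_contest_table()` returns `path` invisibly;
#'   `read_contest_table()` returns a `contest_table` tibble (metadata
#'   attributes restored when the sidecar is present).
#' @export
write_contest_table <- function(table, path) {
  stopifnot(inherits(table, "contest_table"))
  cols <- c("focal_zS", "focal_zB", "focal_zA",
            "opp_zS", "opp_zB", "opp_zA", "w")
  readr::write_csv(as.data.frame(table)[, cols], path)
  p <- attr(table, "params")
  meta <- list(params = unclass(p), n = attr(table, "n"),
               seed = attr(table, "seed"),
               generation = attr(table, "generation"),
               truncation_count = attr(table, "truncation_count"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_contest_table
#' @export
read_contest_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("focal_zS", "focal_zB", "focal_zA",
                "opp_zS", "opp_zB", "opp_zA", "w")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("contest table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("contest_table", class(tab))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tab, "params") <- do.call(contest_params, meta$params)
    attr(tab, "n") <- meta$n
    attr(tab, "seed") <- meta$seed
    attr(tab, "generation") <- meta$generation
    attr(tab, "truncation_count") <- meta$truncation_count
  }
  tab
}
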