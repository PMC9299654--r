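gradient_terms <- c(focal_zS = "betaNS", focal_zB = "betaNB",
                    focal_zA = "betaNA", opp_zS = "betaSS",
                    opp_zB = "betaSB", opp_zA = "betaSA")

check_table_rows <- function(table, min_rows = 50) {
  if (nrow(table) < min_rows) {
    stop("contest table has ", nrow(table), " rows; at least ", min_rows,
         " are required for estimation", call. = FALSE)
  }
}

#' Estimate nonsocial and social selection gradients by multiple regression
#'
#' The selection analysis an empiricist would run on dyadic contest data:
#' ordinary least squares of relative fitness on the focal male's three
#' traits (nonsocial gradients) and his opponent's three traits (social
#' gradients), with an intercept. Because the generator's traits are
#' jointly Gaussian, the partial-regression slopes equal the average
#' derivatives of the (quadratic) fitness surface, so the estimates target
#' the analytic gradients at the generating state.
#'
#' @param table A `contest_table` (>= 50 rows) from [make_contest_table()]
#'   or [read_contest_table()].
#' @param standardize Also report variance-standardised gradients
#'   (multiplied by the predictor standard deviation). Default FALSE; the
#'   model works on natural trait scales.
#' @param condition_threshold Maximum acceptable condition number of the
#'   predictor correlation matrix; beyond it the fit aborts naming the
#'   near-collinear predictors (e.g. when aggression has no intrinsic
#'   variance and is an exact combination of the two signals).
#' @return An object of class `selection_gradient_fit`. Use [tidy()] for
#'   the coefficient table (term, estimate, std.error, statistic, p.value)
#'   and [glance()] for fit diagnostics (`r.squared`, `nobs`,
#'   `condition_number`). Reported standard errors include, by the delta
#'   method, the sampling variance of the within-sample mean-fitness
#'   normalisation (`estimate^2 * var(w) / n`) on top of the OLS term;
#'   for large gradients the scale component dominates.
#' @examples
#' tab <- make_contest_table(2000, population_state(0, 0, 0),
#'                           contest_params(), genetic_architecture(GSB = 0.4),
#'                           seed = 11)
#' tidy(estimate_gradients(tab))
#' @export
estimate_gradients <- function(table, standardize = FALSE,
                               condition_threshold = 1e6) {
  check_table_rows(table)
  X <- as.matrix(table[, names(gradient_terms)])
  cn <- tryCatch(kappa(stats::cor(X), exact = TRUE), error = function(e) Inf)
  if (!is.finite(cn) || cn > condition_threshold) {
    R <- stats::cor(X)
    R[!is.finite(R)] <- 1
    eg <- eigen(R, symmetric = TRUE)
    v <- eg$vectors[, which.min(eg$values)]
    offenders <- names(gradient_terms)[abs(v) > 0.3]
    stop("predictors are (near-)collinear (condition number ",
         format(cn, digits = 3), "): ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(w ~ focal_zS + focal_zB + focal_zA +
                     opp_zS + opp_zB + opp_zA, data = table)
  structure(list(fit = fit, condition_number = cn,
                 standardize = standardize,
                 sds = apply(X, 2, stats::sd),
                 var_w = stats::var(table$w), n = nrow(table)),
            class = "selection_gradient_fit")
}

#' @export
#' @rdname estimate_gradients
#' @param x A `selection_gradient_fit`.
#' @param ... Unused.
tidy.selection_gradient_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  keep <- rownames(sm) %in% names(gradient_terms)
  est <- unname(sm[keep, "Estimate"])
  se_ols <- unname(sm[keep, "Std. Error"])
  # relative fitness is the raw fitness divided by its estimated sample
  # mean; the delta method adds the scale component |beta| * sd(wbar) to
  # the coefficient uncertainty (dominant for large gradients)
  se <- sqrt(se_ols^2 + est^2 * x$var_w / x$n)
  out <- tibble::tibble(
    term = unname(gradient_terms[rownames(sm)[keep]]),
    predictor = rownames(sm)[keep],
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pnorm(-abs(est / se))
  )
  if (isTRUE(x$standardize)) {
    out$estimate_std <- out$estimate * x$sds[out$predictor]
    out$std.error_std <- out$std.error * x$sds[out$predictor]
  }
  out
}

#' @export
#' @rdname estimate_gradients
glance.selection_gradient_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    nobs = stats::nobs(x$fit),
    condition_number = x$condition_number,
    intercept = stats::coef(x$fit)[["(Intercept)"]]
  )
}

#' Estimate the responsiveness of aggression to the signal difference
#'
#' OLS of the focal male's realised aggression on the focal-minus-opponent
#' signal difference. Under the model's assumption that intrinsic
#' aggression is genetically and environmentally uncorrelated with the
#' signal, the slope is an unbiased estimate of `deltaAS`.
#'
#' @param table A `contest_table` (>= 50 rows) with positive variance in
#'   the signal difference.
#' @return An object of class `responsiveness_fit`; [tidy()] gives the
#'   slope row (term `"deltaAS"`), [glance()] the fit summary.
#' @examples
#' tab <- make_contest_table(2000, population_state(0, 0, 0),
#'                           contest_params(deltaAS = 0.4),
#'                           genetic_architecture(GSB = 0.4), seed = 5)
#' tidy(estimate_responsiveness(tab))
#' @export
estimate_responsiveness <- function(table) {
  check_table_rows(table)
  sdiff <- table$focal_zS - table$opp_zS
  if (stats::var(sdiff) <= .Machine$double.eps) {
    stop("signal difference has zero variance: deltaAS is not identifiable",
         call. = FALSE)
  }
  dat <- data.frame(zA = table$focal_zA, sdiff = sdiff)
  fit <- stats::lm(zA ~ sdiff, data = dat)
  structure(list(fit = fit), class = "responsiveness_fit")
}

#' @export
#' @rdname estimate_responsiveness
#' @param x A `responsiveness_fit`.
#' @param ... Unused.
tidy.responsiveness_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = "deltaAS",
    estimate = sm["sdiff", "Estimate"],
    std.error = sm["sdiff", "Std. Error"],
    statistic = sm["sdiff", "t value"],
    p.value = sm["sdiff", "Pr(>|t|)"]
  )
}

#' @export
#' @rdname estimate_responsiveness
glance.responsiveness_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, sigma = sm$sigma,
                 nobs = stats::nobs(x$fit))
}

#' Recover contest cost/benefit coefficients from estimated gradients
#'
#' Inverts the analytic gradient expressions at known population means:
#' `cB = -betaSB / meanA`, `cS = -betaNS / (meanS - thetaS)`, and — given a
#' second gradient fit at a state with a different mean aggression —
#' `(bA, cA)` from the two `betaNA` values (`betaNA = bA - cA * meanA` is
#' linear in the mean). Standard errors are propagated by the delta method
#' treating the population means as known.
#'
#' @param fit A `selection_gradient_fit` estimated at `state`.
#' @param state The [population_state()] at which the table was generated.
#' @param thetaS Naturally selected signal optimum used by the generator.
#' @param fit2,state2 Optional second fit/state with a distinct mean
#'   aggression, enabling the `(bA, cA)` solve.
#' @param tol Means closer to zero than this cannot be divided by; the
#'   error suggests a shifted-state design instead.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @examples
#' st <- population_state(0, 10, 4)
#' tab <- make_contest_table(5000, st, contest_params(),
#'                           genetic_architecture(GSB = 0.4), seed = 9)
#' recover_costs(estimate_gradients(tab), st)
#' @export
recover_costs <- function(fit, state, thetaS = 0, fit2 = NULL, state2 = NULL,
                          tol = 1e-8) {
  stopifnot(inherits(fit, "selection_gradient_fit"),
            inherits(state, "population_state"))
  td <- tidy(fit)
  get <- function(tidy_tab, term) {
    row <- tidy_tab[tidy_tab$term == term, ]
    c(est = row$estimate, se = row$std.error)
  }
  rows <- list()

  if (abs(state$meanA) > tol) {
    bSB <- get(td, "betaSB")
    rows$cB <- tibble::tibble(term = "cB",
                              estimate = -bSB[["est"]] / state$meanA,
                              std.error = bSB[["se"]] / abs(state$meanA))
  } else {
    stop("mean aggression is within tolerance of 0: cB = -betaSB/meanA is ",
         "undefined; generate the table at a state with nonzero mean ",
         "aggression", call. = FALSE)
  }
  dS <- state$meanS - thetaS
  if (abs(dS) > tol) {
    bNS <- get(td, "betaNS")
    rows$cS <- tibble::tibble(term = "cS",
                              estimate = -bNS[["est"]] / dS,
                              std.error = bNS[["se"]] / abs(dS))
  }
  if (!is.null(fit2)) {
    stopifnot(inherits(fit2, "selection_gradient_fit"),
              inherits(state2, "population_state"))
    if (abs(state2$meanA - state$meanA) <= tol) {
      stop("the two states have the same mean aggression: bA and cA are not ",
           "separable; use states with distinct mean aggression",
           call. = FALSE)
    }
    b1 <- get(td, "betaNA")
    b2 <- get(tidy(fit2), "betaNA")
    dA <- state2$meanA - state$meanA
    cA <- (b1[["est"]] - b2[["est"]]) / dA
    cA_se <- sqrt(b1[["se"]]^2 + b2[["se"]]^2) / abs(dA)
    bA <- b1[["est"]] + cA * state$meanA
    # bA = betaNA1 + cA * meanA1 with cA a linear combination of the two
    # independent estimates; propagate accordingly
    wt1 <- 1 + state$meanA / dA
    wt2 <- -state$meanA / dA
    bA_se <- sqrt((wt1 * b1[["se"]])^2 + (wt2 * b2[["se"]])^2)
    rows$cA <- tibble::tibble(term = "cA", estimate = cA, std.error = cA_se)
    rows$bA <- tibble::tibble(term = "bA", estimate = bA, std.error = bA_se)
  }
  dplyr::bind_rows(rows)
}

#' Write an estimation result as JSON
#'
#' Serialises the tidy coefficient table and (when available) the glance
#' diagnostics of a gradient or responsiveness fit.
#'
#' @param fit A `selection_gradient_fit`, `responsiveness_fit`, or a tibble
#'   as returned by [recover_costs()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimation <- function(fit, path) {
  if (inherits(fit, c("selection_gradient_fit", "responsiveness_fit"))) {
    payload <- list(coefficients = tidy(fit), diagnostics = glance(fit))
  } else {
    payload <- list(coefficients = fit)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
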