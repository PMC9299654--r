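#' Genetic architecture of signal, body size and aggression
#'
#' Bundles the additive-genetic and non-heritable (co)variance structure of
#' the three male traits: a signal \eqn{S} (e.g. a weapon or ornament used in
#' contests), body size \eqn{B} (the quality the signal advertises) and
#' intrinsic aggression \eqn{A}. Signal honesty is the genetic covariance
#' `GSB` between signal and body size. Aggression is assumed genetically
#' uncorrelated with both other traits (\eqn{G_{SA} = G_{BA} = 0}); that
#' assumption is structural here, not a default you can override.
#'
#' @param GSS,GBB,GAA Additive-genetic variances of signal, body size and
#'   aggression (trait units squared). Must be non-negative.
#' @param GSB Additive-genetic covariance between signal and body size
#'   (signal honesty). Must satisfy `GSB^2 <= GSS * GBB`.
#' @param ESS,EBB,EAA Non-heritable (environmental plus non-additive)
#'   variances. Must be non-negative.
#' @param ESB Non-heritable signal-body covariance, `ESB^2 <= ESS * EBB`.
#'
#' @return An object of class `genetic_architecture`: a named list with the
#'   eight (co)variance components.
#' @examples
#' G <- genetic_architecture(GSS = 1, GBB = 1, GAA = 1, GSB = 0.4)
#' G_matrix(G)
#' @export
genetic_architecture <- function(GSS = 1, GBB = 1, GAA = 1, GSB = 0,
                                 ESS = 1, EBB = 1, EAA = 1, ESB = 0) {
  vals <- c(GSS = GSS, GBB = GBB, GAA = GAA, GSB = GSB,
            ESS = ESS, EBB = EBB, EAA = EAA, ESB = ESB)
  if (!all(is.finite(vals))) {
    stop("all (co)variance components must be finite numbers", call. = FALSE)
  }
  for (v in c("GSS", "GBB", "GAA", "ESS", "EBB", "EAA")) {
    if (vals[[v]] < 0) stop(sprintf("variance %s must be >= 0", v), call. = FALSE)
  }
  if (GSB^2 > GSS * GBB + 1e-12) {
    stop("|GSB| must not exceed sqrt(GSS * GBB): genetic covariance matrix ",
         "is not positive semidefinite", call. = FALSE)
  }
  if (ESB^2 > ESS * EBB + 1e-12) {
    stop("|ESB| must not exceed sqrt(ESS * EBB)", call. = FALSE)
  }
  structure(as.list(vals), class = "genetic_architecture")
}

#' @rdname genetic_architecture
#' @param G A `genetic_architecture` object.
#' @return `G_matrix()` returns the 3x3 additive-genetic covariance matrix in
#'   trait order (S, B, A); `E_matrix()` the non-heritable analogue.
#' @export
G_matrix <- function(G) {
  stopifnot(inherits(G, "genetic_architecture"))
  matrix(c(G$GSS, G$GSB, 0,
           G$GSB, G$GBB, 0,
           0,     0,     G$GAA),
         3, 3, byrow = TRUE,
         dimnames = list(c("S", "B", "A"), c("S", "B", "A")))
}

#' @rdname genetic_architecture
#' @export
E_matrix <- function(G) {
  stopifnot(inherits(G, "genetic_architecture"))
  matrix(c(G$ESS, G$ESB, 0,
           G$ESB, G$EBB, 0,
           0,     0,     G$EAA),
         3, 3, byrow = TRUE,
         dimnames = list(c("S", "B", "A"), c("S", "B", "A")))
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("<genetic_architecture>\n")
  cat(sprintf("  G: GSS=%g GBB=%g GAA=%g GSB=%g (GSA=GBA=0 by construction)\n",
              x$GSS, x$GBB, x$GAA, x$GSB))
  cat(sprintf("  E: ESS=%g EBB=%g EAA=%g ESB=%g\n",
              x$ESS, x$EBB, x$EAA, x$ESB))
  invisible(x)
}

#' Contest cost/benefit parameters
#'
#' Fitness coefficients of the mechanistic (hawk-dove derived) contest
#' fitness surface, plus the behavioural responsiveness of aggression to the
#' signal difference between rivals.
#'
#' @param bA Fitness benefit of out-aggressing an opponent (per unit
#'   aggression difference). Non-negative.
#' @param cA Cost of mutual aggression (escalated contests). Non-negative;
#'   must be positive for a finite aggression equilibrium to exist.
#' @param cB "Threat of the opponent": cost scaling with the product of the
#'   opponent's aggression and body size. Non-negative.
#' @param cS Strength of natural (stabilising) selection on the signal.
#'   Non-negative.
#' @param thetaS Naturally selected signal optimum (trait units).
#' @param deltaAS Responsiveness of aggression to the focal-minus-opponent
#'   signal difference (dimensionless); the interacting-phenotypes
#'   \eqn{\psi}-like coefficient.
#' @param w0 Fitness intercept.
#'
#' @return An object of class `contest_params`.
#' @examples
#' contest_params(bA = 0.2, cA = 0.05, cB = 0.2, cS = 0.05, deltaAS = 0.4)
#' @export
contest_params <- function(bA = 0.2, cA = 0.05, cB = 0.2, cS = 0.05,
                           thetaS = 0, deltaAS = 0.4, w0 = 1) {
  vals <- c(bA = bA, cA = cA, cB = cB, cS = cS,
            thetaS = thetaS, deltaAS = deltaAS, w0 = w0)
  if (!all(is.finite(vals))) {
    stop("all contest parameters must be finite numbers", call. = FALSE)
  }
  for (v in c("bA", "cA", "cB", "cS")) {
    if (vals[[v]] < 0) stop(sprintf("%s must be >= 0", v), call. = FALSE)
  }
  structure(as.list(vals), class = "contest_params")
}

#' @export
print.contest_params <- function(x, ...) {
  cat("<contest_params>\n")
  cat(sprintf("  bA=%g cA=%g cB=%g cS=%g thetaS=%g deltaAS=%g w0=%g\n",
              x$bA, x$cA, x$cB, x$cS, x$thetaS, x$deltaAS, x$w0))
  invisible(x)
}

#' Population mean state
#'
#' Mean trait (equivalently mean additive-genetic) values at a generation.
#' Mean aggression equals mean intrinsic aggression because the
#' responsiveness term averages to zero over random pairing.
#'
#' @param meanS,meanB,meanA Population mean signal, body size and aggression.
#' @param generation Non-negative integer generation index.
#' @return An object of class `population_state`.
#' @examples
#' population_state(0, 0, 0)
#' @export
population_state <- function(meanS = 0, meanB = 0, meanA = 0, generation = 0L) {
  if (!all(is.finite(c(meanS, meanB, meanA)))) {
    stop("population means must be finite", call. = FALSE)
  }
  if (generation < 0 || generation != round(generation)) {
    stop("generation must be a non-negative integer", call. = FALSE)
  }
  structure(list(meanS = meanS, meanB = meanB, meanA = meanA,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> gen %d: meanS=%g meanB=%g meanA=%g\n",
              x$generation, x$meanS, x$meanB, x$meanA))
  invisible(x)
}

# --- flat key-value configuration files --------------------------------------

config_keys <- function() {
  c("GSS", "GBB", "GAA", "GSB", "ESS", "EBB", "EAA", "ESB",
    "bA", "cA", "cB", "cS", "thetaS", "deltaAS", "w0",
    "z0S", "z0B", "z0A")
}

#' Read and write flat key-value run configurations
#'
#' The configuration format is one `key = value` pair per line, `#` comments
#' allowed. Recognised keys are the genetic (co)variances (`GSS`, `GBB`,
#' `GAA`, `GSB`, `ESS`, `EBB`, `EAA`, `ESB`), the contest coefficients
#' (`bA`, `cA`, `cB`, `cS`, `thetaS`, `deltaAS`, `w0`) and the initial means
#' (`z0S`, `z0B`, `z0A`). Missing keys take the package defaults; unknown
#' keys are an error. `read_run_config()` returns the fully resolved
#' configuration so that writing it back yields a re-runnable file.
#'
#' @param path File path.
#' @return A named list with elements `G` (`genetic_architecture`), `params`
#'   (`contest_params`), `state` (`population_state` at generation 0) and
#'   `values` (the resolved flat key-value vector).
#' @examples
#' cfg_file <- tempfile(fileext = ".cfg")
#' writeLines(c("GSB = 0.4", "deltaAS = 0.4"), cfg_file)
#' cfg <- read_run_config(cfg_file)
#' cfg$params$deltaAS
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  unknown <- setdiff(keys, config_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    stop("non-numeric value for key(s): ",
         paste(keys[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  supplied <- stats::setNames(vals, keys)
  resolve_run_config(as.list(supplied))
}

#' @rdname read_run_config
#' @param overrides Named list of config values; unspecified keys take
#'   package defaults.
#' @export
resolve_run_config <- function(overrides = list()) {
  defaults <- list(
    GSS = 1, GBB = 1, GAA = 1, GSB = 0, ESS = 1, EBB = 1, EAA = 1, ESB = 0,
    bA = 0.2, cA = 0.05, cB = 0.2, cS = 0.05, thetaS = 0, deltaAS = 0.4,
    w0 = 1, z0S = 0, z0B = 0, z0A = 0
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  v <- utils::modifyList(defaults, overrides)
  G <- genetic_architecture(GSS = v$GSS, GBB = v$GBB, GAA = v$GAA,
                            GSB = v$GSB, ESS = v$ESS, EBB = v$EBB,
                            EAA = v$EAA, ESB = v$ESB)
  params <- contest_params(bA = v$bA, cA = v$cA, cB = v$cB, cS = v$cS,
                           thetaS = v$thetaS, deltaAS = v$deltaAS, w0 = v$w0)
  state <- population_state(meanS = v$z0S, meanB = v$z0B, meanA = v$z0A)
  list(G = G, params = params, state = state,
       values = unlist(v[config_keys()]))
}

#' @rdname read_run_config
#' @param config A resolved configuration as returned by `read_run_config()`
#'   or `resolve_run_config()`.
#' @export
write_run_config <- function(config, path) {
  v <- config$values
  writeLines(sprintf("%s = %.17g", names(v), v), path)
  invisible(path)
}
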