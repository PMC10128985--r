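#' Root-mean-square error against a fibroblast reference
#'
#' RMSE between the simulated fibroblast counts at the reference time points
#' and the reference counts. Every reference time must be a recorded tick.
#'
#' @param series a run (or ensemble-mean) series data frame with `tick` and
#'   `fibroblasts`.
#' @param reference data frame with columns `time_h` and `fibroblasts`.
#' @return Scalar RMSE.
#' @export
rmse <- function(series, reference) {
  pos <- match(reference$time_h, series$tick)
  if (anyNA(pos))
    stop("simulation does not cover reference time(s): ",
         paste(reference$time_h[is.na(pos)], collapse = ", "))
  sqrt(mean((series$fibroblasts[pos] - reference$fibroblasts)^2))
}

#' Built-in fibroblast reference time course
#'
#' A synthetic stand-in reference for calibration, anchored at the model's
#' seeded fibroblast count (21) and hard cap (67): counts 21, 39, 67 and 36
#' at 0, 48, 168 and 672 h. Shipped as
#' `extdata/fibroblast_reference_synthetic.csv`; any user CSV with columns
#' `time_h,fibroblasts` can be used instead.
#'
#' @return Data frame with `time_h` and `fibroblasts`.
#' @export
fibroblast_reference <- function() {
  path <- system.file("extdata", "fibroblast_reference_synthetic.csv",
                      package = "myoregen")
  if (nzchar(path)) return(utils::read.csv(path))
  data.frame(time_h = c(0L, 48L, 168L, 672L),
             fibroblasts = c(21L, 39L, 67L, 36L))
}

#' Calibration specification
#'
#' Bundles everything the genetic-algorithm calibration needs: the reference
#' fibroblast time course, per-coefficient box bounds (lower bound 0 for all
#' 31 coefficients; upper bound 1 for the first 25 and 0.5 for the last 6 in
#' the equation-order flattening), the damage condition candidates are
#' evaluated under (5% by default), and the GA hyper-parameters.
#'
#' @param reference data frame (`time_h`, `fibroblasts`); defaults to
#'   [fibroblast_reference()].
#' @param lower,upper numeric length-31 bound vectors.
#' @param damage_mode,damage_fraction evaluation condition.
#' @param pop_size GA population size.
#' @param generations number of GA generations.
#' @param crossover_prob,mutation_prob,mutation_sd,tournament_k GA operators.
#' @param seed GA seed.
#' @return A `calibration_spec` list.
#' @export
calibration_spec <- function(reference = fibroblast_reference(),
                             lower = rep(0, 31L),
                             upper = c(rep(1, 25L), rep(0.5, 6L)),
                             damage_mode = "widespread",
                             damage_fraction = 0.05,
                             pop_size = 24L, generations = 30L,
                             crossover_prob = 0.9, mutation_prob = 0.15,
                             mutation_sd = 0.1, tournament_k = 3L,
                             seed = 1L) {
  stopifnot(length(lower) == 31L, length(upper) == 31L, all(lower <= upper),
            all(c("time_h", "fibroblasts") %in% names(reference)))
  structure(list(reference = reference, lower = lower, upper = upper,
                 damage_mode = damage_mode, damage_fraction = damage_fraction,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, mutation_sd = mutation_sd,
                 tournament_k = as.integer(tournament_k),
                 seed = as.integer(seed)),
            class = "calibration_spec")
}

# simulator-backed objective: run the model with a candidate coefficient
# vector and score the fibroblast trajectory against the reference
.make_sim_objective <- function(spec, base_config, geom) {
  ref_names <- names(default_coefficients())
  function(x) {
    cfg <- base_config
    cfg$coefficients <- coefficient_set(stats::setNames(x, ref_names))
    cfg$damage_mode <- spec$damage_mode
    cfg$damage_fraction <- spec$damage_fraction
    sim <- try(run_simulation(cfg, geom, run_seed = cfg$seed), silent = TRUE)
    if (inherits(sim, "try-error")) return(Inf)
    rmse(sim$series, spec$reference)
  }
}

#' Calibrate the 31 production coefficients by genetic algorithm
#'
#' Real-coded GA (tournament selection, blend crossover, Gaussian mutation,
#' elitism) over the 31-dimensional coefficient box. Each candidate is
#' evaluated by running the simulator at the specification's damage
#' condition and scoring the fibroblast time course with [rmse()]; with
#' elitism the best RMSE is non-increasing across generations. A candidate
#' whose simulation fails scores worst-possible fitness.
#'
#' @param spec a [calibration_spec()].
#' @param base_config [sim_config()] used for candidate evaluation (its
#'   duration must cover the reference times).
#' @param geom evaluation geometry (`NULL` = default reference; calibration
#'   is usually run on a reduced geometry for speed).
#' @param objective optional objective `function(x) -> scalar` replacing the
#'   simulator-backed one (used for testing the optimiser itself).
#' @param seed_candidates optional list of coefficient vectors injected into
#'   the initial population (e.g. `list(default_coefficients())`).
#' @return List with `coefficients` (named best vector), `rmse` (best
#'   score), `history` (per-generation best), `evaluations`.
#' @export
ga_optimise <- function(spec, base_config = sim_config(), geom = NULL,
                        objective = NULL, seed_candidates = NULL) {
  if (is.null(objective)) {
    if (is.null(geom)) geom <- default_geometry(seed = 1L)
    objective <- .make_sim_objective(spec, base_config, geom)
  }
  lo <- spec$lower
  hi <- spec$upper
  d <- length(lo)
  np <- spec$pop_size
  clamp <- function(x) pmin(pmax(x, lo), hi)
  with_seed(spec$seed, {
    pop <- lapply(seq_len(np), function(i) lo + stats::runif(d) * (hi - lo))
    if (!is.null(seed_candidates)) {
      k <- min(length(seed_candidates), np)
      for (i in seq_len(k)) pop[[i]] <- clamp(as.numeric(seed_candidates[[i]]))
    }
    fit <- vapply(pop, objective, numeric(1))
    n_eval <- np
    history <- numeric(spec$generations + 1L)
    history[1L] <- min(fit)
    for (g in seq_len(spec$generations)) {
      newpop <- vector("list", np)
      best <- which.min(fit)
      newpop[[1L]] <- pop[[best]] # elitism
      for (i in 2:np) {
        pick <- function() {
          cand <- sample.int(np, spec$tournament_k)
          pop[[cand[which.min(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (stats::runif(1) < spec$crossover_prob) {
          a <- stats::runif(d, -0.1, 1.1) # blend (BLX-ish) crossover
          clamp(a * p1 + (1 - a) * p2)
        } else p1
        mut <- stats::runif(d) < spec$mutation_prob
        if (any(mut))
          child[mut] <- clamp(child + stats::rnorm(d, 0, spec$mutation_sd *
                                                     (hi - lo)))[mut]
        newpop[[i]] <- child
      }
      newfit <- c(fit[best], vapply(newpop[-1L], objective, numeric(1)))
      n_eval <- n_eval + np - 1L
      pop <- newpop
      fit <- newfit
      history[g + 1L] <- min(fit)
    }
    best <- which.min(fit)
    list(coefficients = stats::setNames(pop[[best]],
                                        names(default_coefficients())),
         rmse = fit[best], history = history, evaluations = n_eval)
  })
}

#' Write a calibration report
#'
#' JSON with the best coefficient vector, its RMSE and the per-generation
#' best-RMSE history.
#'
#' @param result a [ga_optimise()] result.
#' @param path JSON path.
#' @export
save_calibration <- function(result, path) {
  jsonlite::write_json(list(coefficients = as.list(result$coefficients),
                            rmse = result$rmse, history = result$history,
                            evaluations = result$evaluations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
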