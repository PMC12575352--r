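#' Sparse rat IV sampling schedule
#'
#' The eight-point post-dose sampling design used for the rat validation
#' study: 0, 15, 45, 60, 90, 120, 180 and 240 minutes, in hours.
#'
#' @return Numeric vector of times in h.
#' @export
rat_schedule <- function() {
  c(0, 15, 45, 60, 90, 120, 180, 240) / 60
}

#' Generate a reproducible panel of fentanyl-class compound parameter sets
#'
#' Draws `n` analog parameter sets spanning the property ranges of the
#' compound class: logP uniform on `logp_range` (default 1.4-4.5), fup
#' log-uniform on `fup_range` (default 0.05-0.35), blood:plasma ratio
#' uniform on `rbp_range` (default 0.8-1.1), basic pKa uniform on
#' `pka_range` (default 7.5-9.5). Unless per-compound clearances are
#' supplied, every analog carries the shared reference clearance (the
#' batch-workflow convention for this class).
#'
#' @param n Panel size (>= 1).
#' @param seed Integer seed; same seed, same panel.
#' @param logp_range,fup_range,rbp_range,pka_range Sampling ranges.
#' @param clsys Shared clearance, L/h.
#' @param species Species tag for all panel members.
#' @return Named list of `compound_properties` (`analog_01`, ...), with the
#'   drawn parameters also attached as a data.frame attribute `"panel"`.
#' @export
gen_compound_panel <- function(n, seed, logp_range = c(1.4, 4.5),
                               fup_range = c(0.05, 0.35),
                               rbp_range = c(0.8, 1.1),
                               pka_range = c(7.5, 9.5),
                               clsys = 62.66, species = "human") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  for (r in list(logp_range, fup_range, rbp_range, pka_range)) {
    if (length(r) != 2L || r[1] >= r[2]) stop("invalid range", call. = FALSE)
  }
  if (any(fup_range <= 0) || fup_range[2] > 1) {
    stop("fup_range must lie in (0, 1]", call. = FALSE)
  }
  rng <- local_rng(seed)
  logp <- rng$runif(n, logp_range[1], logp_range[2])
  fup <- exp(rng$runif(n, log(fup_range[1]), log(fup_range[2])))
  rbp <- rng$runif(n, rbp_range[1], rbp_range[2])
  pka <- rng$runif(n, pka_range[1], pka_range[2])

  tab <- data.frame(name = sprintf("analog_%02d", seq_len(n)),
                    logp = logp, fup = fup, rbp = rbp, pka = pka,
                    clsys = clsys, species = species)
  out <- lapply(seq_len(n), function(i) {
    compound_properties(name = tab$name[i], logp = tab$logp[i],
                        pka = tab$pka[i], pka_type = "base",
                        fup = tab$fup[i], rbp = tab$rbp[i],
                        clsys = clsys, species = species)
  })
  names(out) <- tab$name
  attr(out, "panel") <- tab
  out
}

#' Generate a synthetic observed study from a PBPK model
#'
#' Simulates the model noise-free, samples the plasma series at `schedule`,
#' and produces `n_subjects` observed profiles by applying independent
#' multiplicative lognormal assay noise (median 1, coefficient of variation
#' `noise_cv`) to every sampled point. Values below `lloq` are dropped, not
#' zeroed. The noise-free truth (simulation and its NCA) is retained so
#' downstream recovery can be scored against it.
#'
#' @param model A [build_model()] result.
#' @param schedule Sampling times in h (default the eight-point rat design).
#' @param noise_cv Assay coefficient of variation (>= 0).
#' @param n_subjects Number of replicate subjects.
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @param lloq Lower limit of quantification, pg/mL (observations below are
#'   dropped).
#' @param t_end,n_points Passed to [simulate_pbpk()] for the truth run.
#' @return An object of class `synthetic_study`: `truth` (list with `sim`,
#'   `nca`, `model`), `schedule`, `noise_cv`, `n_subjects`, `seed`, `lloq`,
#'   and `observed` (list of [conc_profile()]s).
#' @export
gen_observed_study <- function(model, schedule = rat_schedule(),
                               noise_cv = 0.15, n_subjects = 1, seed = 1,
                               lloq = 0, t_end = NULL, n_points = NULL) {
  stopifnot(inherits(model, "pbpk_model"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  sim <- simulate_pbpk(model, t_end = t_end, n_points = n_points)
  if (max(schedule) > max(sim$time) || min(schedule) < 0) {
    stop("schedule lies outside the simulated span", call. = FALSE)
  }
  truth_conc <- stats::approx(sim$time, sim$conc["plasma", ],
                              xout = schedule)$y
  truth_profile <- conc_profile(schedule[-1], truth_conc[-1], dose = sim$dose,
                                label = "plasma_truth_at_schedule")
  # full-grid truth is the reference for parameter-recovery scoring
  truth_nca <- nca_iv(sim_profile(sim))

  sdlog <- sqrt(log(1 + noise_cv^2))
  rng <- local_rng(seed)
  observed <- lapply(seq_len(n_subjects), function(s) {
    mult <- if (noise_cv > 0) {
      exp(rng$rnorm(length(schedule), mean = 0, sd = sdlog))
    } else {
      rep(1, length(schedule))
    }
    obs <- truth_conc * mult
    keep <- obs >= lloq
    conc_profile(schedule[keep], obs[keep], dose = sim$dose,
                 label = sprintf("subject_%03d", s))
  })

  structure(
    list(truth = list(sim = sim, nca = truth_nca, model = model,
                      profile_at_schedule = truth_profile),
         schedule = schedule, noise_cv = noise_cv,
         n_subjects = n_subjects, seed = seed, lloq = lloq,
         observed = observed),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s: %d subjects, %d sampling times, noise CV %.2g, seed %d\n",
              x$truth$model$compound$name, x$n_subjects, length(x$schedule),
              x$noise_cv, x$seed))
  invisible(x)
}

# seed-scoped RNG: draws do not disturb (and are not disturbed by) the
# global .Random.seed
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single integer", call. = FALSE)
  env <- new.env()
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(env$state)) {
      set.seed(as.integer(seed))
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(runif = function(...) run(stats::runif, ...),
       rnorm = function(...) run(stats::rnorm, ...))
}
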