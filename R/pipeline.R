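#' Batch PBPK workflow over a compound panel
#'
#' Runs the standardized analog workflow for every compound in `compounds`:
#' obtain a Kp set (supplied per compound, or predicted from tissue
#' composition), build and simulate the model under a shared dose regimen,
#' run NCA on plasma, and summarize tissue exposure. Per-compound failures
#' are caught, logged in `failures`, and do not stop the batch.
#'
#' The report ranks compounds by brain/plasma Cmax ratio; when `reference`
#' names a batch member, each row is flagged `"higher"`/`"lower"` than the
#' reference's ratio (ties `"equal"`).
#'
#' @param compounds Named list of [compound_properties()] (e.g. from
#'   [gen_compound_panel()] or [load_compound_table()]).
#' @param physiology A `species_physiology` shared by the batch.
#' @param regimen A [dose_regimen()] shared by the batch.
#' @param kp Optional named list of `kp_set`s keyed by compound name;
#'   compounds without an entry get [predict_kp_composition()].
#' @param reference Optional name of the reference compound for ranking.
#' @param t_end,n_points Passed to [simulate_pbpk()].
#' @param store_sims Keep full simulation objects in the result.
#' @return List with `report` (one data.frame row per compound, ranked),
#'   `results` (per-compound `nca`, `ratios`, optionally `sim`), `failures`.
#' @export
run_batch <- function(compounds, physiology, regimen, kp = NULL,
                      reference = NULL, t_end = NULL, n_points = NULL,
                      store_sims = FALSE) {
  stopifnot(is.list(compounds), length(compounds) >= 1L)
  results <- list()
  failures <- character()
  rows <- list()
  for (nm in names(compounds)) {
    res <- tryCatch({
      cmp <- compounds[[nm]]
      kset <- if (!is.null(kp) && nm %in% names(kp)) {
        kp[[nm]]
      } else {
        predict_kp_composition(cmp, species = physiology$species)
      }
      model <- build_model(physiology, cmp, kset, regimen)
      sim <- simulate_pbpk(model, t_end = t_end, n_points = n_points)
      nca <- nca_iv(sim_profile(sim))
      ratios <- tissue_ratios(sim)
      br <- ratios[ratios$tissue == "brain", ]
      rows[[nm]] <- data.frame(
        name = nm, kp_source = kset$source,
        auc_0_inf = nca$auc_0_inf, cl = nca$cl, vss = nca$vss,
        t_half = nca$t_half, cmax_plasma = max(sim$conc["plasma", ]),
        brain_plasma_cmax = br$cmax_ratio, brain_plasma_auc = br$auc_ratio)
      out <- list(nca = nca, ratios = ratios, kp = kset)
      if (store_sims) out$sim <- sim
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      message("batch: ", nm, " failed: ", conditionMessage(res))
    } else {
      results[[nm]] <- res
    }
  }
  if (!length(rows)) stop("every compound in the batch failed", call. = FALSE)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report <- report[order(-report$brain_plasma_cmax), , drop = FALSE]
  if (!is.null(reference)) {
    if (!reference %in% report$name) {
      stop("reference compound not in batch: ", reference, call. = FALSE)
    }
    ref_ratio <- report$brain_plasma_cmax[report$name == reference]
    report$ratio_vs_reference <- report$brain_plasma_cmax / ref_ratio
    report$vs_reference <- ifelse(
      report$brain_plasma_cmax > ref_ratio, "higher",
      ifelse(report$brain_plasma_cmax < ref_ratio, "lower", "equal"))
  }
  list(report = report, results = results, failures = failures)
}

#' Dual-Kp-source model comparison for one compound
#'
#' Builds and simulates two models that differ only in their Kp source,
#' reports side-by-side NCA and algebraic Vss, and (if an observed profile
#' is supplied) fold errors of each model against the observation.
#'
#' @param physiology A `species_physiology`.
#' @param compound A [compound_properties()].
#' @param kp_a,kp_b Two `kp_set`s for the same species (e.g. extrapolated
#'   vs composition/table).
#' @param regimen A [dose_regimen()].
#' @param observed Optional observed [conc_profile()].
#' @param labels Column labels for the two sets (default their sources).
#' @param t_end,n_points Passed to [simulate_pbpk()].
#' @return List with `comparison` (data.frame, one row per PK parameter,
#'   one column per Kp set), `nca` (both results), `vss_algebraic` (both),
#'   and `fold_errors` per set when `observed` is given.
#' @export
run_dual_kp_compare <- function(physiology, compound, kp_a, kp_b, regimen,
                                observed = NULL, labels = NULL,
                                t_end = NULL, n_points = NULL) {
  if (is.null(labels)) labels <- make.unique(c(kp_a$source, kp_b$source))
  sets <- stats::setNames(list(kp_a, kp_b), labels)
  ncas <- list()
  vss_alg <- numeric()
  fes <- list()
  for (lab in labels) {
    model <- build_model(physiology, compound, sets[[lab]], regimen)
    sim <- simulate_pbpk(model, t_end = t_end, n_points = n_points)
    ncas[[lab]] <- nca_iv(sim_profile(sim))
    vss_alg[lab] <- vss_algebraic(sets[[lab]], physiology, compound$rbp)
    if (!is.null(observed)) {
      fes[[lab]] <- compare_profiles(sim_profile(sim), observed)$fold_errors
    }
  }
  params <- c("auc_0_t", "auc_0_inf", "cl", "vss", "t_half", "cmax")
  comparison <- data.frame(parameter = c(params, "vss_algebraic"))
  for (lab in labels) {
    comparison[[lab]] <- c(vapply(params, function(p) ncas[[lab]][[p]],
                                  numeric(1)),
                           vss_alg[[lab]])
  }
  out <- list(comparison = comparison, nca = ncas, vss_algebraic = vss_alg)
  if (!is.null(observed)) out$fold_errors <- fes
  out
}

#' Write a reproducibility manifest for a run
#'
#' Records every scalar input, the seed, package and R versions, and md5
#' digests of any referenced input files, as JSON.
#'
#' @param path Output JSON path.
#' @param inputs Named list of run inputs (scalars/vectors).
#' @param files Character vector of input file paths to digest.
#' @param seed Seed used for any randomness.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), files = character(),
                               seed = NA_integer_) {
  manifest <- list(
    package = "opbpk",
    package_version = as.character(utils::packageVersion("opbpk")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = inputs,
    file_md5 = as.list(tools::md5sum(files[file.exists(files)])))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
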