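#' Construct a tissue/blood partition coefficient set
#'
#' A `kp_set` maps each of the 13 canonical tissue compartments to a
#' tissue-to-blood partition coefficient (Kp), tagged with the compound,
#' species and provenance of the values.
#'
#' @param kp Named numeric vector covering every tissue in [kp_tissues()];
#'   all values > 0.
#' @param compound Compound name.
#' @param species `"rat"` or `"human"`.
#' @param source One of `"table"`, `"composition_qsar"`, `"extrapolated"`.
#' @return An object of class `kp_set`.
#' @export
kp_set <- function(kp, compound, species = c("rat", "human"),
                   source = c("table", "composition_qsar", "extrapolated")) {
  species <- match.arg(species)
  source <- match.arg(source)
  kp <- canonicalize_kp(kp)
  structure(list(compound = as.character(compound), species = species,
                 source = source, kp = kp),
            class = "kp_set")
}

# normalize tissue names (case/space/hyphen-insensitive), check coverage and
# positivity; returns the vector reordered to canonical order
canonicalize_kp <- function(kp) {
  if (is.null(names(kp))) stop("kp must be a named vector", call. = FALSE)
  nm <- normalize_tissue_name(names(kp))
  unknown <- setdiff(nm, kp_tissues())
  if (length(unknown)) {
    stop("unknown tissue name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(kp_tissues(), nm)
  if (length(missing)) {
    stop("incomplete Kp set; missing tissue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  names(kp) <- nm
  kp <- kp[kp_tissues()]
  if (any(!is.finite(kp)) || any(kp <= 0)) {
    stop("all Kp values must be finite and > 0", call. = FALSE)
  }
  kp
}

normalize_tissue_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ /-]+", "_", x)
  x
}

#' Load a Kp table from CSV or a packaged fixture
#'
#' Reads a two-column CSV (`tissue,kp`) into a [kp_set()] with
#' `source = "table"`. The rows of the published Kp table for
#' beta-hydroxythiofentanyl and fentanyl ship as fixtures addressable by id:
#' `"bht_rat_qsar"`, `"fentanyl_rat_report"`, `"fentanyl_rat_qsar"`,
#' `"fentanyl_human_extrapolated"`, `"fentanyl_human_qsar"`.
#'
#' @param path_or_id Path to a CSV file, or one of the fixture ids above.
#' @param compound Compound name; inferred from a fixture id if omitted.
#' @param species Species; inferred from a fixture id if omitted.
#' @return A `kp_set` with `source = "table"`.
#' @export
load_kp_table <- function(path_or_id, compound = NULL, species = NULL) {
  fixtures <- kp_fixture_registry()
  if (path_or_id %in% names(fixtures)) {
    fx <- fixtures[[path_or_id]]
    path <- system.file("extdata", fx$file, package = "opbpk", mustWork = TRUE)
    if (is.null(compound)) compound <- fx$compound
    if (is.null(species)) species <- fx$species
  } else {
    path <- path_or_id
    if (!file.exists(path)) {
      stop("not a packaged Kp fixture id and file does not exist: ",
           path_or_id, call. = FALSE)
    }
    if (is.null(compound)) compound <- sub("\\.[^.]*$", "", basename(path))
    if (is.null(species)) {
      stop("species must be given when loading a Kp file by path",
           call. = FALSE)
    }
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("tissue", "kp") %in% names(tab))) {
    stop("Kp file must have columns tissue,kp", call. = FALSE)
  }
  kp <- stats::setNames(tab$kp, tab$tissue)
  kp_set(kp, compound = compound, species = species, source = "table")
}

kp_fixture_registry <- function() {
  list(
    bht_rat_qsar = list(file = "kp_bht_rat_qsar.csv",
                        compound = "beta_hydroxythiofentanyl", species = "rat"),
    fentanyl_rat_report = list(file = "kp_fentanyl_rat_report.csv",
                               compound = "fentanyl", species = "rat"),
    fentanyl_rat_qsar = list(file = "kp_fentanyl_rat_qsar.csv",
                             compound = "fentanyl", species = "rat"),
    fentanyl_human_extrapolated = list(file = "kp_fentanyl_human_extrapolated.csv",
                                       compound = "fentanyl", species = "human"),
    fentanyl_human_qsar = list(file = "kp_fentanyl_human_qsar.csv",
                               compound = "fentanyl", species = "human"))
}

#' Extrapolate a rat Kp set to human
#'
#' Applies the standard fraction-unbound / blood:plasma-ratio interspecies
#' scaling to every tissue:
#' \deqn{Kp_{human,t} = \frac{fup_{human}}{fup_{rat}} \cdot
#'       \frac{BP_{rat}}{BP_{human}} \cdot Kp_{rat,t}}
#' The operation is exactly linear and tissue-wise independent.
#'
#' @param kp_rat A rat `kp_set`.
#' @param fup_rat,fup_human Fractions unbound in plasma (percent-scale input
#'   accepted with a warning, see [parse_fraction()]).
#' @param bp_rat,bp_human Blood:plasma concentration ratios, > 0.
#' @return A human `kp_set` with `source = "extrapolated"`.
#' @export
extrapolate_kp <- function(kp_rat, fup_rat, fup_human, bp_rat, bp_human) {
  stopifnot(inherits(kp_rat, "kp_set"))
  if (kp_rat$species != "rat") {
    stop("extrapolate_kp expects a rat Kp set", call. = FALSE)
  }
  fup_rat <- parse_fraction(fup_rat, "fup_rat")
  fup_human <- parse_fraction(fup_human, "fup_human")
  for (v in c(bp_rat = bp_rat, bp_human = bp_human)) {
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      stop("blood:plasma ratios must be positive", call. = FALSE)
    }
  }
  s <- (fup_human / fup_rat) * (bp_rat / bp_human)
  kp_set(kp_rat$kp * s, compound = kp_rat$compound, species = "human",
         source = "extrapolated")
}

#' @export
print.kp_set <- function(x, ...) {
  cat(sprintf("<kp_set> %s, %s, source=%s\n", x$compound, x$species, x$source))
  print(round(x$kp, 3))
  invisible(x)
}
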