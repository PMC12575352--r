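#' Construct a compound parameter set
#'
#' Bundles the physicochemical and binding parameters a perfusion-limited
#' PBPK model needs: octanol-water logP, ionization constants, fraction
#' unbound in plasma (fup), blood:plasma concentration ratio (rbp), and a
#' plasma-referenced systemic clearance. Water solubility and jejunal
#' permeability are carried as metadata (unused for the intravenous route).
#'
#' Fraction-unbound values are stored as fractions in (0, 1]. Literature
#' tables for this compound class often print fup on the percent scale
#' (e.g. 32.25 or "32.25%"); values > 1 (or with a `%` suffix, via
#' [parse_fraction()]) are converted with a warning to prevent silent
#' hundred-fold errors.
#'
#' @param name Compound name.
#' @param logp Octanol-water log partition coefficient.
#' @param pka Numeric vector of ionization constants.
#' @param pka_type Character vector, `"acid"`/`"base"`, same length as `pka`.
#' @param fup Fraction unbound in plasma, in (0, 1] (percent-scale input
#'   converted with a warning).
#' @param rbp Blood:plasma concentration ratio, > 0.
#' @param clsys Plasma-referenced systemic clearance, L/h (>= 0).
#' @param species `"rat"` or `"human"`.
#' @param sw Water solubility, mg/mL (metadata).
#' @param peff Effective jejunal permeability, 1e-4 cm/s (metadata).
#' @return An object of class `compound_properties`.
#' @export
compound_properties <- function(name, logp, pka = numeric(), pka_type = character(),
                                fup, rbp, clsys = 0,
                                species = c("rat", "human"),
                                sw = NA_real_, peff = NA_real_) {
  species <- match.arg(species)
  fup <- parse_fraction(fup, what = "fup")
  stopifnot(length(logp) == 1L, is.finite(logp))
  if (length(pka) != length(pka_type)) {
    stop("pka and pka_type must have equal length", call. = FALSE)
  }
  if (length(pka_type) && !all(pka_type %in% c("acid", "base"))) {
    stop("pka_type entries must be 'acid' or 'base'", call. = FALSE)
  }
  if (!is.numeric(rbp) || length(rbp) != 1L || !is.finite(rbp) || rbp <= 0) {
    stop("rbp must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(clsys) || length(clsys) != 1L || !is.finite(clsys) || clsys < 0) {
    stop("clsys must be a single nonnegative number (L/h)", call. = FALSE)
  }
  structure(
    list(name = as.character(name), logp = logp,
         pka = as.numeric(pka), pka_type = as.character(pka_type),
         fup = fup, rbp = rbp, clsys = clsys, species = species,
         sw = sw, peff = peff),
    class = "compound_properties")
}

#' Parse a fraction that may arrive on the percent scale
#'
#' Accepts a bare fraction in (0, 1], a percent-scale number > 1, or a string
#' with a `%` suffix; percent-scale inputs are divided by 100 with a warning.
#'
#' @param x Numeric or character scalar.
#' @param what Label used in messages.
#' @return A fraction in (0, 1].
#' @export
parse_fraction <- function(x, what = "fraction") {
  if (is.character(x)) {
    pct <- grepl("%\\s*$", x)
    x <- as.numeric(sub("%\\s*$", "", x))
    if (pct) {
      # an explicit % suffix is unambiguous: convert silently
      if (!is.finite(x) || x <= 0 || x > 100) {
        stop(what, " percent value out of range", call. = FALSE)
      }
      return(x / 100)
    }
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive number", call. = FALSE)
  }
  if (x > 1) {
    if (x > 100) stop(what, " = ", x, " is not interpretable as a fraction or percent",
                      call. = FALSE)
    warning(sprintf("%s = %g interpreted as percent; converting to %g", what, x, x / 100),
            call. = FALSE)
    x <- x / 100
  }
  x
}

#' @export
print.compound_properties <- function(x, ...) {
  cat(sprintf("<compound_properties> %s (%s): logP %.2f, fup %.3f, rbp %.2f, CLsys %.3g L/h\n",
              x$name, x$species, x$logp, x$fup, x$rbp, x$clsys))
  invisible(x)
}

#' Load the packaged compound parameter table
#'
#' Reads the bundled per-compound fixture table (or a user CSV with the same
#' columns) and returns one `compound_properties` per row, plus dosing
#' metadata as attributes `dose_ug` and `body_weight_kg`.
#'
#' @param file Optional replacement CSV path.
#' @return Named list of `compound_properties` (names `"<compound>_<species>"`).
#' @export
load_compound_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "compounds.csv", package = "opbpk",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    cp <- compound_properties(
      name = row$name, logp = row$logp,
      pka = row$pka, pka_type = row$pka_type,
      fup = row$fup, rbp = row$rbp, clsys = row$clsys_L_h,
      species = row$species, sw = row$sw_mg_ml, peff = row$peff_1e4_cm_s)
    attr(cp, "dose_ug") <- row$dose_ug
    attr(cp, "body_weight_kg") <- row$body_weight_kg
    attr(cp, "provenance") <- row$provenance
    cp
  })
  names(out) <- paste(tab$name, tab$species, sep = "_")
  out
}
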