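#' Canonical tissue compartment names
#'
#' The 13 perfused tissue compartments of the whole-body model, in canonical
#' order. Arterial and venous blood are carried separately.
#'
#' @return Character vector of 13 tissue names.
#' @export
kp_tissues <- function() {
  c("lung", "adipose", "muscle", "liver", "spleen", "heart", "brain",
    "kidney", "skin", "reproductive_organs", "red_marrow", "yellow_marrow",
    "rest_of_body")
}

blood_compartments <- function() c("arterial_blood", "venous_blood")

#' Load species physiology (compartment volumes and perfusion flows)
#'
#' Returns the reference whole-body physiology for `species`, linearly
#' rescaled so that all volumes and flows scale with `body_weight` relative
#' to the reference animal (0.25 kg rat, 70 kg human). The packaged reference
#' tables are compendium values; a user CSV with columns
#' `compartment,volume_L,flow_L_per_h` may be substituted via `file`.
#'
#' Topology conventions: the lung is in series and carries the full cardiac
#' output; spleen outflow is routed through the liver (splanchnic routing);
#' `rest_of_body` closes the volume and flow balance, so the non-lung tissue
#' flows sum to cardiac output.
#'
#' @param species `"rat"` or `"human"`.
#' @param body_weight Body weight in kg; defaults to the reference weight.
#' @param file Optional path to a replacement physiology CSV.
#' @param scaling_exponent Allometric exponent for the rescaling (default 1,
#'   i.e. volumes and flows proportional to body weight).
#' @return An object of class `species_physiology`: a list with `species`,
#'   `body_weight` (kg), `cardiac_output` (L/h) and `compartments` (a
#'   data.frame `compartment,volume_L,flow_L_per_h`).
#' @export
get_physiology <- function(species = c("rat", "human"), body_weight = NULL,
                           file = NULL, scaling_exponent = 1) {
  species <- match.arg(species)
  ref_bw <- switch(species, rat = 0.25, human = 70)
  if (is.null(body_weight)) body_weight <- ref_bw
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a single positive number", call. = FALSE)
  }
  if (is.null(file)) {
    file <- system.file("extdata", paste0("physiology_", species, ".csv"),
                        package = "opbpk", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("compartment", "volume_L", "flow_L_per_h")
  if (!all(need %in% names(tab))) {
    stop("physiology file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  expected <- c(kp_tissues(), blood_compartments())
  missing <- setdiff(expected, tab$compartment)
  if (length(missing)) {
    stop("physiology file missing compartments: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[match(expected, tab$compartment), , drop = FALSE]
  rownames(tab) <- NULL

  k <- (body_weight / ref_bw)^scaling_exponent
  tab$volume_L <- tab$volume_L * k
  tab$flow_L_per_h <- tab$flow_L_per_h * k
  co <- tab$flow_L_per_h[tab$compartment == "lung"]

  phys <- structure(
    list(species = species, body_weight = body_weight,
         cardiac_output = co, compartments = tab),
    class = "species_physiology")
  validate_physiology(phys)
  phys
}

#' Validate a species_physiology object
#'
#' Checks positivity, lung flow = cardiac output, venous-return closure of the
#' non-lung tissue flows within 1%, and the whole-body mass-balance bound
#' (total volume at most body weight / body density).
#'
#' @param phys A `species_physiology`.
#' @param body_density Assumed whole-body density, kg/L.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys, body_density = 1.0) {
  stopifnot(inherits(phys, "species_physiology"))
  tab <- phys$compartments
  if (any(tab$volume_L <= 0) || any(tab$flow_L_per_h <= 0)) {
    stop("all compartment volumes and flows must be strictly positive",
         call. = FALSE)
  }
  co <- phys$cardiac_output
  lung_q <- tab$flow_L_per_h[tab$compartment == "lung"]
  if (abs(lung_q - co) > 1e-9 * co) {
    stop("lung flow must equal cardiac output (series lung)", call. = FALSE)
  }
  nonlung <- setdiff(kp_tissues(), "lung")
  qsum <- sum(tab$flow_L_per_h[tab$compartment %in% nonlung])
  if (abs(qsum - co) > 0.01 * co) {
    stop(sprintf(
      "venous-return closure violated: non-lung tissue flows sum to %.4g L/h vs cardiac output %.4g L/h",
      qsum, co), call. = FALSE)
  }
  vtot <- sum(tab$volume_L)
  if (vtot > phys$body_weight / body_density + 1e-9) {
    stop(sprintf("total compartment volume %.4g L exceeds body weight bound %.4g L",
                 vtot, phys$body_weight / body_density), call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s, %.3g kg, cardiac output %.3g L/h\n",
              x$species, x$body_weight, x$cardiac_output))
  print(x$compartments, row.names = FALSE)
  invisible(x)
}

# volume/flow lookup helpers used across modules
phys_volume <- function(phys, compartment) {
  tab <- phys$compartments
  tab$volume_L[match(compartment, tab$compartment)]
}

phys_flow <- function(phys, compartment) {
  tab <- phys$compartments
  tab$flow_L_per_h[match(compartment, tab$compartment)]
}
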