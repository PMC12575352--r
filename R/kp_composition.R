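#' Predict tissue/blood partition coefficients from tissue composition
#'
#' Mechanistic Kp prediction using the Rodgers-Rowland tissue-composition
#' equations. Compounds whose strongest basic pKa is >= 7 at blood pH
#' (the fentanyl class) use the moderate-to-strong base equation, in which
#' the ionized species binds tissue acidic phospholipids with an affinity
#' calibrated from blood-cell partitioning (via rbp, fup and hematocrit).
#' Neutrals, acids and weak bases use the extended equation in which the
#' unionized species binds tissue neutral lipid/phospholipid and
#' albumin-class proteins (scaled by the tissue:plasma binding-protein
#' ratio). For adipose-like tissues the neutral-lipid partition uses a
#' vegetable-oil/water logD surrogate (1.115*logP - 1.35).
#'
#' Predicted unbound tissue:plasma coefficients are converted to the
#' tissue:blood scale via `Kp = Kpu * fup / rbp`. The result carries
#' `source = "composition_qsar"`; the packaged published Kp tables remain
#' the canonical route for reproducing reported outputs.
#'
#' @param compound A [compound_properties()].
#' @param species `"rat"` or `"human"` (defaults to the compound's tag).
#' @param ph_plasma Plasma pH for ionization (default 7.4).
#' @param composition_file Optional replacement tissue-composition CSV.
#' @return A `kp_set` with `source = "composition_qsar"`.
#' @export
predict_kp_composition <- function(compound, species = compound$species,
                                   ph_plasma = 7.4, composition_file = NULL) {
  stopifnot(inherits(compound, "compound_properties"))
  species <- match.arg(species, c("rat", "human"))
  if (compound$fup <= 0 || compound$fup > 1) {
    stop("fup must be in (0, 1]", call. = FALSE)
  }
  comp <- load_tissue_composition(composition_file)
  cst <- rr_constants(species)

  P <- 10^compound$logp
  # vegetable-oil surrogate for adipose neutral lipid
  D_vo <- 10^(1.115 * compound$logp - 1.35)

  X_p <- ion_ratio(compound, ph_plasma)          # plasma
  X_iw <- ion_ratio(compound, cst$ph_iw)         # intracellular water
  X_bc <- ion_ratio(compound, cst$ph_bc)         # blood cell
  base_pkas <- compound$pka[compound$pka_type == "base"]
  strong_base <- length(base_pkas) && max(base_pkas) >= 7

  fup <- compound$fup
  rbp <- compound$rbp
  hct <- cst$hct
  # unbound blood-cell:plasma partition from measured whole-blood binding
  kpu_bc <- (rbp - (1 - hct)) / (hct * fup)

  lip <- function(p, f_nl, f_np) p * f_nl + (0.3 * p + 0.7) * f_np

  kp <- vapply(seq_len(nrow(comp)), function(i) {
    t <- comp[i, ]
    adipose_like <- t$tissue %in% c("adipose", "yellow_marrow")
    p_t <- if (adipose_like) D_vo else P
    water <- t$f_ew + ((1 + X_iw) / (1 + X_p)) * t$f_iw
    lipid <- lip(p_t, t$f_nl, t$f_np) / (1 + X_p)
    if (strong_base) {
      ka_ap <- (kpu_bc - ((1 + X_bc) / (1 + X_p)) * cst$f_iw_bc -
                  lip(P, cst$f_nl_bc, cst$f_np_bc) / (1 + X_p)) *
        (1 + X_p) / (cst$ap_bc * X_bc)
      ka_ap <- max(ka_ap, 0)
      extra <- ka_ap * t$ap_mg_g * X_iw / (1 + X_p)
    } else {
      # albumin-class binding inferred from plasma unbound fraction
      prot_p <- max(1 / fup - 1 - lip(P, cst$f_nl_p, cst$f_np_p) / (1 + X_p), 0)
      extra <- prot_p * t$pr_ratio
    }
    kpu <- water + lipid + extra
    kpu * fup / rbp
  }, numeric(1))
  names(kp) <- comp$tissue

  kp_set(kp, compound = compound$name, species = species,
         source = "composition_qsar")
}

load_tissue_composition <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "tissue_composition.csv",
                        package = "opbpk", mustWork = TRUE)
  }
  comp <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g", "pr_ratio")
  if (!all(need %in% names(comp))) {
    stop("tissue composition file must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  missing <- setdiff(kp_tissues(), comp$tissue)
  if (length(missing)) {
    stop("tissue composition missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  comp[match(kp_tissues(), comp$tissue), , drop = FALSE]
}

# ionized:unionized concentration ratio at a given pH, summed over sites
ion_ratio <- function(compound, ph) {
  x <- 0
  for (i in seq_along(compound$pka)) {
    x <- x + if (compound$pka_type[i] == "base") {
      10^(compound$pka[i] - ph)
    } else {
      10^(ph - compound$pka[i])
    }
  }
  x
}

# species constants for the composition method: intracellular and blood-cell
# pH, hematocrit, and plasma / blood-cell lipid fractions
rr_constants <- function(species) {
  list(ph_iw = 7.0, ph_bc = 7.22,
       hct = switch(species, rat = 0.46, human = 0.45),
       f_nl_p = 0.0023, f_np_p = 0.0013,
       f_iw_bc = 0.603, f_nl_bc = 0.0017, f_np_bc = 0.0029,
       ap_bc = 0.5)
}
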