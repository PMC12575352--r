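# shared fixtures, built once per test run
phys_rat <- get_physiology("rat", 0.25)
phys_human <- get_physiology("human", 70)
compounds <- load_compound_table()

fentanyl_human <- compounds[["fentanyl_human"]]
bht_rat <- compounds[["beta_hydroxythiofentanyl_rat"]]
acetylfentanyl_human <- compounds[["acetylfentanyl_human"]]

kp_fent_human_qsar <- load_kp_table("fentanyl_human_qsar")
kp_fent_human_extrap <- load_kp_table("fentanyl_human_extrapolated")
kp_fent_rat_report <- load_kp_table("fentanyl_rat_report")
kp_bht <- load_kp_table("bht_rat_qsar")

# uniform Kp set (all tissues at `value`)
uniform_kp <- function(value = 1, compound = "test", species = "rat") {
  kp_set(stats::setNames(rep(value, 13), kp_tissues()),
         compound = compound, species = species)
}

# compound with clearance replaced
with_clsys <- function(cmp, clsys) {
  compound_properties(cmp$name, cmp$logp, cmp$pka, cmp$pka_type, cmp$fup,
                      cmp$rbp, clsys = clsys, species = cmp$species)
}
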