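# Per-compound physicochemistry, binding and clearance fixtures.
# fup/rbp as fractions/ratios; clsys plasma-referenced L/h at the stated
# body weight; dose_ug absolute IV dose. provenance: table = printed source
# table; shared_clearance = fentanyl's measured human CL_sys reused across
# analogs (printed via the acetylfentanyl row); synthetic_representative =
# value not printed anywhere, chosen as a representative fentanyl-class
# number and so marked.
name,species,logp,pka,pka_type,fup,rbp,sw_mg_ml,peff_1e4_cm_s,clsys_L_h,dose_ug,body_weight_kg,provenance
beta_hydroxythiofentanyl,rat,2.59,8.9,base,0.3225,1.04,0.48,3.35,0.9,1.75,0.25,table+synthetic_representative
fentanyl,rat,4.05,8.77,base,0.083,1.01,0.20,4.0,0.9,1.75,0.25,table+synthetic_representative
fentanyl,human,4.05,8.77,base,0.255,1.01,0.20,4.0,62.66,100,70,table+shared_clearance
acetylfentanyl,human,3.55,8.9,base,0.168,0.83,0.59,3.81,62.66,100,70,table+shared_clearance
sufentanil,human,3.85,8.0,base,0.0891,1.0,0.08,4.0,58.55,490,70,table+synthetic_representative
alfentanil,human,2.26,6.5,base,0.1579,1.0,0.50,4.0,53.931,490,70,table+synthetic_representative
remifentanil,human,1.95,7.1,base,0.2657,1.0,1.0,4.0,58.553,490,70,table+synthetic_representative
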