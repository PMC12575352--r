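# Reference whole-body physiology, adult human male, 70 kg.
# Compendium-style values (Brown et al. 1997 tier, rounded); cardiac output 312 L/h.
# arterial_blood / venous_blood carry total (cardiac output) flow.
# rest_of_body closes the mass/flow balance to 0.96*BW total volume.
compartment,volume_L,flow_L_per_h
lung,0.5,312
adipose,15.0,16.2
muscle,28.0,53.0
liver,1.8,67.1
spleen,0.18,3.7
heart,0.33,12.5
brain,1.43,35.6
kidney,0.31,54.6
skin,2.6,18.1
reproductive_organs,0.035,1.6
red_marrow,1.1,9.4
yellow_marrow,2.4,2.5
rest_of_body,8.315,37.7
arterial_blood,1.7,312
venous_blood,3.5,312
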