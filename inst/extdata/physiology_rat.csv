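# Reference whole-body physiology, adult male Sprague-Dawley rat, 0.25 kg.
# Compendium-style values (Brown et al. 1997 tier, rounded); cardiac output 4.8 L/h.
# arterial_blood / venous_blood carry total (cardiac output) flow.
# rest_of_body closes the mass/flow balance to 0.96*BW total volume.
compartment,volume_L,flow_L_per_h
lung,0.00125,4.8
adipose,0.019,0.336
muscle,0.101,1.334
liver,0.00915,0.787
spleen,0.0005,0.048
heart,0.00083,0.235
brain,0.0014,0.096
kidney,0.00183,0.677
skin,0.0475,0.278
reproductive_organs,0.0025,0.024
red_marrow,0.00625,0.144
yellow_marrow,0.00125,0.029
rest_of_body,0.03039,0.812
arterial_blood,0.0055,4.8
venous_blood,0.0129,4.8
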