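# Predicted-vs-observed PK parameter pairs for clinically characterized
# analogs (intravenous route). Units: t_half h, vss L, cl L/h.
analog,parameter,predicted,observed,unit
sufentanil,t_half,3.652,2.73,h
sufentanil,vss,308.601,119,L
alfentanil,t_half,0.93,1.21,h
alfentanil,cl,53.931,31.44,L/h
remifentanil,t_half,0.571,0.17,h
remifentanil,t_half,0.571,0.24,h
remifentanil,t_half,0.571,0.26,h
remifentanil,t_half,0.571,0.34,h
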