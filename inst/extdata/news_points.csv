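# National Early Warning Score component points, v1 (NEWS, 2012 version)
# Source: Royal College of Physicians. National Early Warning Score (NEWS):
# Standardising the assessment of acute-illness severity in the NHS. RCP 2012.
# Intervals are half-open [lower, upper); avpu is coded A=0, V=1, P=2, U=3;
# supp_o2 is coded 0 (room air) / 1 (supplemental oxygen).
component,lower,upper,points
rr,-Inf,9,3
rr,9,12,1
rr,12,21,0
rr,21,25,2
rr,25,Inf,3
spo2,-Inf,92,3
spo2,92,94,2
spo2,94,96,1
spo2,96,Inf,0
supp_o2,0,1,0
supp_o2,1,Inf,2
temp,-Inf,35.1,3
temp,35.1,36.1,1
temp,36.1,38.1,0
temp,38.1,39.1,1
temp,39.1,Inf,2
sbp,-Inf,91,3
sbp,91,101,2
sbp,101,111,1
sbp,111,220,0
sbp,220,Inf,3
hr,-Inf,41,3
hr,41,51,1
hr,51,91,0
hr,91,111,1
hr,111,131,2
hr,131,Inf,3
avpu,0,1,0
avpu,1,Inf,3
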