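# Modified Early Warning Score component points, v1
# Source: Subbe CP, Kruger M, Rutherford P, Gemmel L. Validation of a modified
# Early Warning Score in medical admissions. QJM 2001;94(10):521-526.
# Intervals are half-open [lower, upper); avpu is coded A=0, V=1, P=2, U=3.
component,lower,upper,points
sbp,-Inf,71,3
sbp,71,81,2
sbp,81,101,1
sbp,101,200,0
sbp,200,Inf,2
hr,-Inf,41,2
hr,41,51,1
hr,51,101,0
hr,101,111,1
hr,111,130,2
hr,130,Inf,3
rr,-Inf,9,2
rr,9,15,0
rr,15,21,1
rr,21,30,2
rr,30,Inf,3
temp,-Inf,35,2
temp,35,38.5,0
temp,38.5,Inf,2
avpu,0,1,0
avpu,1,2,1
avpu,2,3,2
avpu,3,Inf,3
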