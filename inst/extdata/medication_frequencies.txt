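# Medication dosing-frequency terms (lowercase match against the surface
# form of FREQUENCY-type time expressions).
bid
tid
qid
prn
qd
qod
qhs
qam
qpm
q2h
q4h
q6h
q8h
q12h
daily
nightly
twice daily
three times daily
every other day
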