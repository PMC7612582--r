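# Default in-silico mitochondrial stress-test protocol.
# Counters are assay minutes on the 0-100 clock; a drug key set to "none"
# omits that injection.  "lag" is the settling window excluded after each
# injection before plateaus are measured.
oligomycin = 20
fccp = 50
rot_aa = 80
duration = 100
lag = 5
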