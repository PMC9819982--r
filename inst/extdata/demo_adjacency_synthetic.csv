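"region_a","region_b"
"R01","R02"
"R02","R03"
"R03","R04"
"R04","R05"
"R05","R06"
"R06","R01"
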