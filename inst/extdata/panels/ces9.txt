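# ces9: simplified CES panel for HG-U133A-restricted meta-analyses.
# Equals ces14 minus the five genes lacking HG-U133A probes
# (CENPW, CENPL, CENPK, SPC24, NUF2).
CENPA
CENPN
CENPM
CENPU
ZWINT
HJURP
MIS18B
NDC80
SPC25
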