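# ces14: 14-gene core CES panel (consistently tumour-overexpressed genes with
# prognostic evidence). Twelve members are named in the primary description;
# CENPU and ZWINT are synthetic stand-ins for the two members listed only in
# supplementary material (see package documentation).
CENPA
CENPN
CENPM
CENPK
CENPL
CENPW
CENPU
ZWINT
HJURP
MIS18B
NDC80
NUF2
SPC24
SPC25
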