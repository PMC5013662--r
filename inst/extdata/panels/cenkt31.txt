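# cenkt31: 31 centromere/kinetochore structural and assembly genes.
# CENP-A + CCAN subunits + KMN network (KNL1, MIS12 and NDC80 complexes)
# + CENP-A assembly factors. Synthetic stand-in reconstructed from the
# published structural description; see package documentation.
CENPA
CENPC
CENPT
CENPW
CENPS
CENPX
CENPN
CENPL
CENPM
CENPH
CENPI
CENPK
CENPO
CENPP
CENPQ
CENPR
CENPU
KNL1
ZWINT
MIS12
DSN1
NSL1
PMF1
NDC80
NUF2
SPC24
SPC25
HJURP
MIS18A
MIS18B
MIS18BP1
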