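# observed monoisotopic peak list: rat metal-binding-domain analog
# [Acetyl]-DAEFGHDSGFEVRHQK-[Amide] after 60 min with the ACE C-domain
# (reflector positive mode; intensities are representative)
mz,intensity
1507.5,38
1644.9,21
1772.9,12
1899.9,100
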