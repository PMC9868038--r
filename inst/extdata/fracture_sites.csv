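icd10_prefix,site
S72,hip
S220,vertebrae
S320,vertebrae
M484,vertebrae
M485,vertebrae
S223,nvnh
S224,nvnh
S321,nvnh
S325,nvnh
S422,nvnh
S52,nvnh
S821,nvnh
S02,excluded_site
S625,excluded_site
S626,excluded_site
S627,excluded_site
S924,excluded_site
S925,excluded_site
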