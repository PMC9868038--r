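drug_code,drug_class,default_days_supply
alendronate,bisphosphonate,30
risedronate,bisphosphonate,30
minodronate,bisphosphonate,30
ibandronate,bisphosphonate,30
zoledronic_acid,bisphosphonate,365
alfacalcidol,active_vitamin_D3,30
calcitriol,active_vitamin_D3,30
eldecalcitol,active_vitamin_D3,30
teriparatide_ra,teriparatide,28
teriparatide_ac,teriparatide,28
denosumab,denosumab,180
raloxifene,SERM,30
bazedoxifene,SERM,30
elcatonin,calcitonin,30
estriol,estrogen,30
menatetrenone,vitamin_K2,30
calcium_aspartate,calcium,30
ipriflavone,ipriflavone,30
nandrolone,nandrolone,30
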