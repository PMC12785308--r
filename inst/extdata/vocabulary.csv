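variant,canonical
alopecia areata,alopecia_areata
aa,alopecia_areata
androgenetic alopecia,androgenetic_alopecia
aga,androgenetic_alopecia
male pattern baldness,androgenetic_alopecia
telogen effluvium,telogen_effluvium
te,telogen_effluvium
lichen planopilaris,lichen_planopilaris
lpp,lichen_planopilaris
frontal fibrosing alopecia,frontal_fibrosing_alopecia
ffa,frontal_fibrosing_alopecia
central centrifugal cicatricial alopecia,ccca
ccca,ccca
tinea capitis,tinea_capitis
trichotillomania,trichotillomania
traction alopecia,traction_alopecia
seborrheic dermatitis,seborrheic_dermatitis
scalp psoriasis,scalp_psoriasis
discoid lupus erythematosus,discoid_lupus
dle,discoid_lupus
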