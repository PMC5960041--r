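canonical,variants,acronyms,category
aids carrier,,,living with hiv
aids victim,,,living with hiv
hiv carrier,,,living with hiv
hiv victim,,,living with hiv
hiv positive,,,living with hiv
hiv infected,,,living with hiv
aids patient,,,living with hiv
hiv aids patient,hiv/aids patient,,living with hiv
living with hiv,,,living with hiv
people living with hiv,,plhiv,living with hiv
gay,,,homosexual
homosexual,,,homosexual
men who have sex with men,,msm,msm
prostitute,,,sex worker
sex worker,,,sex worker
drug addict,,,alcohol and drug use
drug abuser,,,alcohol and drug use
drug abuse,,,alcohol and drug use
people who use drugs,,,alcohol and drug use
people who inject drugs,,,alcohol and drug use
seniors,,,older adults
older patient,,,older adults
antiretroviral therapy,,art,antiretroviral therapy
combination antiretroviral therapy,,cart,antiretroviral therapy
highly active antiretroviral therapy,,haart,antiretroviral therapy
aids cocktail,,,antiretroviral therapy
hiv cocktail,,,antiretroviral therapy
pre exposure prophylaxis,pre-exposure prophylaxis,prep,pre-exposure prophylaxis and post-exposure prophylaxis
post exposure prophylaxis,post-exposure prophylaxis,pep,pre-exposure prophylaxis and post-exposure prophylaxis
treatment as prevention,,tasp,pre-exposure prophylaxis and post-exposure prophylaxis
aids epidemic,,,epidemic
hiv epidemic,,,epidemic
treatment interruption,,,treatment interruption
structured treatment interruption,,,treatment interruption
stopping treatment,,,treatment interruption
treatment experienced,,,treatment interruption
drug holiday,,,treatment interruption
continuum of care,,,care continuum
hiv care continuum,,,care continuum
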