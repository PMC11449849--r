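site,doi,metric,unit,scan1,scan2,published_cv
buccal_mucosa,DOI 1,VAD,percent,49.58,50.05,0.0047
buccal_mucosa,DOI 1,VSD,percent,7.12,7.38,0.0179
buccal_mucosa,DOI 1,VDI,um,85.65,84.95,0.0041
buccal_mucosa,DOI 1,WTI,unitless,12.86,12.40,0.0257
buccal_mucosa,DOI 2,VAD,percent,47.58,47.59,0.0001
buccal_mucosa,DOI 2,VSD,percent,6.27,6.26,0.0008
buccal_mucosa,DOI 2,VDI,um,91.89,91.48,0.0022
buccal_mucosa,DOI 2,WTI,unitless,21.34,20.77,0.0194
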