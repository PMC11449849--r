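site,n,doi,metric,unit,mean,sd,lower95,upper95
buccal_mucosa,32,DOI 1,VAD,percent,43.32,8.12,40.39,46.25
buccal_mucosa,32,DOI 1,VSD,percent,6.55,1.33,6.08,7.03
buccal_mucosa,32,DOI 1,VDI,um,74.50,10.79,70.61,78.38
buccal_mucosa,32,DOI 1,WTI,unitless,20.45,3.16,19.31,21.59
buccal_mucosa,32,DOI 2,VAD,percent,41.17,6.73,38.75,43.60
buccal_mucosa,32,DOI 2,VSD,percent,5.64,1.04,5.27,6.02
buccal_mucosa,32,DOI 2,VDI,um,83.09,9.64,79.61,86.57
buccal_mucosa,32,DOI 2,WTI,unitless,22.17,2.23,21.37,22.97
labial_mucosa,24,DOI 1,VAD,percent,49.97,5.18,47.78,52.16
labial_mucosa,24,DOI 1,VSD,percent,6.64,0.86,6.28,7.00
labial_mucosa,24,DOI 1,VDI,um,87.76,9.20,83.88,91.65
labial_mucosa,24,DOI 1,WTI,unitless,18.86,3.16,17.53,20.20
labial_mucosa,24,DOI 2,VAD,percent,44.11,5.46,41.81,46.42
labial_mucosa,24,DOI 2,VSD,percent,4.89,0.79,4.55,5.23
labial_mucosa,24,DOI 2,VDI,um,108.41,13.48,102.71,114.10
labial_mucosa,24,DOI 2,WTI,unitless,16.82,2.62,15.71,17.92
floor_of_mouth,13,DOI 1,VAD,percent,52.00,5.28,48.81,55.19
floor_of_mouth,13,DOI 1,VSD,percent,5.68,1.09,5.02,6.33
floor_of_mouth,13,DOI 1,VDI,um,120.21,23.07,106.27,134.15
floor_of_mouth,13,DOI 1,WTI,unitless,17.18,2.05,15.94,18.41
floor_of_mouth,13,DOI 2,VAD,percent,53.98,5.93,50.40,57.57
floor_of_mouth,13,DOI 2,VSD,percent,4.64,0.61,4.27,5.01
floor_of_mouth,13,DOI 2,VDI,um,161.67,31.62,142.57,180.78
floor_of_mouth,13,DOI 2,WTI,unitless,15.41,2.07,14.09,16.73
hard_palate,8,DOI 1,VAD,percent,33.19,6.07,28.12,38.27
hard_palate,8,DOI 1,VSD,percent,4.33,1.25,3.29,5.37
hard_palate,8,DOI 1,VDI,um,85.25,8.88,77.82,92.67
hard_palate,8,DOI 1,WTI,unitless,23.39,4.89,19.30,27.48
hard_palate,8,DOI 2,VAD,percent,35.83,4.92,31.71,39.95
hard_palate,8,DOI 2,VSD,percent,3.94,0.96,3.13,4.74
hard_palate,8,DOI 2,VDI,um,114.90,26.53,92.72,137.07
hard_palate,8,DOI 2,WTI,unitless,19.69,3.87,16.45,22.93
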