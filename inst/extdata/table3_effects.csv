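taxon,beta_geo,se_geo,ri_geo,in_final_model
SESA,-1.10,0.45,1.00,TRUE
WESA,-0.99,0.67,0.52,TRUE
RNPH,-0.79,0.77,0.37,TRUE
DUNLsch,-0.24,0.44,0.28,TRUE
SANDrub,1.03,0.46,0.72,TRUE
DUNLhud,0.39,0.48,0.22,TRUE
DUNLpac,-0.70,0.39,0.60,TRUE
DUNLarc,-0.66,0.31,0.82,TRUE
SANDalb,0,NA,NA,FALSE
GSAP,0.46,0.20,1.00,TRUE
GTTA,0,NA,NA,FALSE
RUTUint,-0.52,0.32,0.58,TRUE
RUTUmor,0.49,0.67,0.35,TRUE
BLTU,-0.33,0.31,0.11,TRUE
REKNrog,0,NA,NA,FALSE
REKNruf,0.20,0.19,0.37,TRUE
AMGP,0.44,0.41,0.20,TRUE
GRSN,0.20,0.36,0.28,TRUE
GRKN,0.74,0.37,0.73,TRUE
BTGO,-0.29,0.38,0.32,TRUE
WHIMhud,0.35,0.35,0.24,TRUE
WHIMisl,1.38,0.46,0.67,TRUE
FECU,1.51,0.76,1.00,TRUE
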