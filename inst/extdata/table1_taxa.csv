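taxon,common_name,n_sites,n_control_captures,n_geo_captures,mean_body_mass_g,migration_deg_lat,attachment,geo_total_mass_g,geo_pct_body_mass,max_pct_all_tags
SESA,Semipalmated sandpiper,7,949,224,26,65,"PEF,PAB",0.9,3.6,5.8
WESA,Western sandpiper,1,276,21,27,49,PAB,1.0,3.7,5.2
RNPH,Red-necked phalarope,1,21,7,38,66,LLH,1.0,2.6,NA
DUNLsch,schinzii dunlin,1,64,30,46,45,PAB,0.8,1.8,2.5
SANDrub,rubida sanderling,1,55,44,53,111,PEF,0.8,1.5,NA
DUNLhud,hudsonia dunlin,1,133,35,57,20,PEF,1.1,1.9,2.9
DUNLpac,pacifica dunlin,3,57,124,57,27,PEF,1.1,1.9,2.9
DUNLarc,arcticola dunlin,3,255,104,58,30,PEF,1.1,1.9,3.3
SANDalb,alba sanderling,3,434,30,59,60,PEF,0.8,1.4,2.3
GSAP,Greater sand plover,1,289,59,87,58,PEF,0.9,1.0,1.8
GTTA,Gray-tailed tattler,1,160,19,104,88,PAF,1.3,1.3,2.0
RUTUint,interpres ruddy turnstone,1,112,77,105,113,PEF,0.9,0.9,NA
RUTUmor,morinella ruddy turnstone,3,62,46,109,70,PEF,0.9,0.8,1.6
BLTU,Black turnstone,1,51,30,123,9,LLH,2.0,1.6,2.3
REKNrog,rogersi red knot,1,11,26,125,108,PAB,1.4,1.1,1.8
REKNruf,rufa red knot,2,711,87,132,100,PAB,1.55,1.2,1.6
AMGP,American golden-plover,5,55,129,146,94,PEF,1.1,0.75,1.6
GRSN,Great snipe,1,34,45,160,64,PAB,1.3,0.8,NA
GRKN,Great knot,1,126,64,195,81,PEF,0.8,0.4,0.8
BTGO,Bar-tailed godwit,1,16,58,342,105,PAB,1.8,0.5,1.6
WHIMhud,hudsonicus whimbrel,1,31,25,378,54,PAF,1.0,0.3,NA
WHIMisl,islandicus whimbrel,1,56,23,438,58,PAF,1.0,0.2,NA
FECU,Far eastern curlew,1,7,23,1091,90,PEF,1.0,0.1,0.3
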