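name,lipid_class,tail1_length,tail2_length,double_bonds1,double_bonds2
DLPC,PC,12,12,0,0
DPPC,PC,16,16,0,0
DSPC,PC,18,18,0,0
POPC,PC,16,18,0,1
DOPC,PC,18,18,1,1
DAPC,PC,20,20,4,4
DLPE,PE,12,12,0,0
DPPE,PE,16,16,0,0
POPE,PE,16,18,0,1
DOPE,PE,18,18,1,1
DAPE,PE,20,20,4,4
DPPS,PS,16,16,0,0
POPS,PS,16,18,0,1
DOPS,PS,18,18,1,1
DAPS,PS,20,20,4,4
DPPI,PI,16,16,0,0
POPI,PI,16,18,0,1
DOPI,PI,18,18,1,1
DPPG,PG,16,16,0,0
POPG,PG,16,18,0,1
DOPG,PG,18,18,1,1
DPPA,PA,16,16,0,0
POPA,PA,16,18,0,1
DOPA,PA,18,18,1,1
DPSM,SM,16,18,0,0
DXSM,SM,24,18,0,0
POSM,SM,16,18,0,1
DPCE,CER,16,18,0,0
DXCE,CER,24,18,0,0
POCE,CER,16,18,0,1
DPMG,MG,16,16,0,0
OPMG,MG,16,18,0,1
FPMG,MG,16,22,0,4
DPDG,DG,16,16,0,0
PODG,DG,16,18,0,1
DODG,DG,18,18,1,1
FA08,FA,8,0,0,0
FA12,FA,12,0,0,0
FA16,FA,16,0,0,0
FA18,FA,18,0,0,0
FA181,FA,18,0,1,0
FA204,FA,20,0,4,0
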