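branch,expert,objective,method
top,Fish,ecological state,add
top,BioB,ecological state,mult
top,BioPhys,ecological state,mult
top,Phys,ecological state,add
physical,Phys,physical state sub-objectives,add
physical,Phys,morphology and hydraulics sub-objectives,add
physical,Phys,discharge sub-objectives,add
physical,Phys,bed-moving and floodplain floods,add
physical,Phys,connectivity sub-objectives,add
physical,authors,barrier height and power stations,add
physical,unspecified,flow dynamics,add
physical,BioPhys,physical state sub-objectives,mult
physical,BioPhys,morphology and hydraulics sub-objectives,mult
physical,BioPhys,discharge sub-objectives,mult
physical,Fish,natural discharge regime sub-objectives,mult
physical,Fish,flood dynamics sub-objectives,mult
physical,BioPhys,connectivity sub-objectives,mult
physical,Fish,artificial flow management sub-objectives,mult
chemical,Phys,physico-chemical state sub-objectives,add
chemical,Phys,suspended solids sub-objectives,add
chemical,BioPhys,physico-chemical state sub-objectives,mult
chemical,Fish,temperature regime sub-objectives,mult
chemical,BioPhys,temperature regime sub-objectives,mult
biological,BioA,ground and rove beetle densities,add
biological,BioA,biological state sub-objectives,mult
biological,BioB,biological state sub-objectives,mult
biological,BioPhys,biological state sub-objectives,mult
biological,BioB,ecosystem function sub-objectives,mult
biological,BioPhys,ecosystem function sub-objectives,mult
biological,BioC,ecosystem stability sub-objectives,mult
biological,BioB,biodiversity sub-objectives,mult
biological,BioPhys,biodiversity sub-objectives,mult
biological,Fish,fish community sub-objectives,mult
biological,Fish,trout population sub-objectives,mult
biological,Fish,barbel and chub population sub-objectives,mult
biological,Fish,nase population sub-objectives,mult
biological,Fish,fish community structure,mult
biological,BioA,benthic organism sub-objectives,mult
biological,BioB,benthic organism sub-objectives,mult
biological,BioA,functional feeding groups,mult
biological,BioB,functional feeding groups,mult
biological,BioA,community indices,mult
biological,BioB,floodplain vegetation sub-objectives,mult
biological,BioPhys,floodplain vegetation sub-objectives,mult
biological,BioA,shoreline fauna sub-objectives,mult
biological,BioPhys,organic cycle sub-objectives,mult
biological,BioPhys,spring respiration and production,mult
biological,BioPhys,summer respiration and production,mult
biological,BioPhys,fall respiration and production,mult
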