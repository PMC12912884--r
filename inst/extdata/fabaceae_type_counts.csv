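category,level,n
native_status,near_endemic,18
native_status,native_non_endemic,64
native_status,strict_endemic,44
growth_form,annual_or_biennial_herb,27
growth_form,perennial_herb,26
growth_form,perennial_climbing_herb,1
growth_form,shrub_or_subshrub,44
growth_form,tree,25
growth_form,woody_climber,3
iucn,CR,4
iucn,EN,6
iucn,VU,14
iucn,NT,1
iucn,LC,46
iucn,DD,9
iucn,NE,46
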