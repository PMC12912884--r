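category,unit_name,n
IPA,All IPAs combined,33
CoE,Chimanimani-Nyanga,11
CoE,Inhambane,14
CoE,Lebombo Mountains,11
CoE,Maputaland,37
CoE,Rovuma,48
CoE,South East African Montane Archipelago,22
ecoregion,Central Zambezian Wet Miombo Woodlands,3
ecoregion,Dry Miombo Woodlands,67
ecoregion,Limpopo Lowveld,9
ecoregion,Maputaland Coastal Forests and Woodlands,47
ecoregion,Southern Swahili Coastal Forests and Woodlands,78
ecoregion,Zambezian Coastal Flooded Savanna,10
ecoregion,Zambezian Limpopo Mixed Woodlands,26
ecoregion,Zambezian Mopane Woodlands,18
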