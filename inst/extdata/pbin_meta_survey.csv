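study,bacteria_source,bacteria,phage_source,phages,fill,temperature,nested,phi_printed
study_01,Laboratory,7,Sewage,3,71.4,0,yes,1
study_02,Sewage water,8,Manure,5,55,1.1,yes,1
study_03,Laboratory,17,Non-fecal compost,4,42.6,21.5,yes,3
study_04,"Laboratory, soil",19,Soil,4,68.4,6.2,yes,1
study_05,"Poultry, laboratory",16,"Poultry, sewage, soil",6,31.3,11.4,yes,2
study_06,Clinical,20,Sewage,5,52,27.8,yes,3
study_07,Laboratory,36,Prophage induction,3,64.8,47.1,no,4
study_08,Laboratory,12,"Manure, cattle feed, water, soil",10,51.7,17.7,yes,2
study_09,Air,5,Air,25,15.2,31,no,3
study_10,"Potato, laboratory",42,River water,3,90.4,0,yes,1
study_11,"Food, water, laboratory",42,Sewage,3,62.7,0,yes,1
study_12,Kiwifruit,31,Soil,5,25.7,18.3,yes,4
study_13,Livestock,20,Sewage,10,92,10.3,no,2
study_14,"Orchid, wastewater",55,"Orchid, wastewater",4,25,7.5,yes,4
study_15,"Dairy, laboratory",26,"Manure, sewage, laboratory",10,33.4,21.8,yes,4
study_16,Equine,27,Soil,10,57.4,15.7,yes,3
study_17,Seafood,50,Laboratory,6,84.7,1,yes,1
study_18,Laboratory,27,"Fermented food, soil",12,44.4,22.3,yes,3
study_19,Human feces,15,Sewage,22,72.4,5.8,yes,1
study_20,Laboratory,12,Sewage,29,49.4,10.2,yes,2
study_21,Clinical,60,Sewage,6,32.8,6,yes,3
study_22,"Clinical, cattle feces",54,Cattle,7,89.7,0,yes,1
study_23,Walnut,16,Walnut,26,71.6,12.6,yes,2
study_24,"Cattle, human",41,Cattle feces,11,20.2,23.8,yes,5
study_25,Dairy,20,Dairy,24,31.5,37.3,yes,4
study_26,"Laboratory, mushroom",34,Mushroom,16,39.3,12.8,yes,3
study_27,Dairy,44,Livestock feces,26,30.2,15.2,yes,4
study_28,"Vegetable, seafood, livestock",31,Prophage,39,21.6,11.6,yes,4
study_29,"Dairy, laboratory",56,Fecal,26,45.6,17.4,yes,4
study_30,Livestock,47,Livestock,36,14.3,10.2,yes,5
study_31,Laboratory,113,Prophage,19,6.2,11.6,yes,7
study_32,Beehive,40,Beehive,57,40.7,7.7,yes,3
study_33,Pork meat,72,Prophage,41,22.1,13.7,yes,5
study_34,"Clinical, poultry",64,"Poultry, sewage",50,18.7,18.2,yes,6
study_35,Feces,75,Feces,166,6.1,2.8,yes,5
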