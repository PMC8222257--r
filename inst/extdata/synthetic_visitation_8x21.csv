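"species","pollinator_01","pollinator_02","pollinator_03","pollinator_04","pollinator_05","pollinator_06","pollinator_07","pollinator_08","pollinator_09","pollinator_10","pollinator_11","pollinator_12","pollinator_13","pollinator_14","pollinator_15","pollinator_16","pollinator_17","pollinator_18","pollinator_19","pollinator_20","pollinator_21"
"plant_01",0,0,0,0,1,0,3,0,0,0,11,0,0,23,0,0,0,1,30,0,0
"plant_02",0,0,0,0,0,0,0,2,0,0,0,0,0,2,0,0,0,0,1,0,0
"plant_03",0,0,0,0,0,0,0,0,1,4,0,0,0,10,1,0,0,5,1,4,1
"plant_04",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,3,0,0
"plant_05",0,5,5,0,0,0,0,9,2,2,0,0,0,5,0,1,1,0,0,0,0
"plant_06",0,1,0,0,0,0,0,0,2,0,0,0,1,0,0,0,0,0,0,1,0
"plant_07",0,0,0,2,0,0,0,1,0,0,10,0,1,1,0,0,0,56,0,11,0
"plant_08",0,0,0,0,1,0,0,0,0,1,0,0,3,0,0,0,0,0,13,0,0
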