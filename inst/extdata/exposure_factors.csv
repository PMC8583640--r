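# Published exposure factors: overall ("average") and per age group
# body_weight kg; food_ingestion g/day; soil_ingestion mg/day; water_intake mL/day
group,parameter,unit,median,mean
average,body_weight,kg,25,27
average,food_ingestion,g/day,548,545
average,soil_ingestion,mg/day,41,51
average,water_intake,mL/day,1104,1083
y3_6,body_weight,kg,17,19
y3_6,food_ingestion,g/day,513,494
y3_6,soil_ingestion,mg/day,40,36
y3_6,water_intake,mL/day,953,937
y7_12,body_weight,kg,32,30
y7_12,food_ingestion,g/day,612,595
y7_12,soil_ingestion,mg/day,66,62
y7_12,water_intake,mL/day,1238,1254
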