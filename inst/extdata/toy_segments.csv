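procedure_id,phase,start_s,end_s
demo1,Preparation,0,120
demo1,Calot triangle dissection,120,1050
demo1,Clipping and cutting,1050,1230
demo1,Gallbladder dissection,1230,2100
demo1,Gallbladder packaging,2100,2190
demo1,Cleaning and coagulation,2190,2370
demo1,Gallbladder retraction,2370,2460
demo2,Preparation,0,150
demo2,Calot triangle dissection,150,1350
demo2,Clipping and cutting,1350,1500
demo2,Gallbladder dissection,1500,2250
demo2,Gallbladder packaging,2250,2340
demo2,Cleaning and coagulation,2340,2520
demo2,Gallbladder retraction,2520,2600
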