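metabolite	s01	s02	s03	s04	s05	s06	s07	s08
L-carnitine	974.2	671	1558.1	993.7	969.4	944.4	609.8	598
butyrate	191.6	237.5	514.7	314.1	586	481	602.1	312.2
caproate	449.6	171.8	216.8	298.7	366.5	557.6	765.2	224.1
biotin	463.2	613.8	816.8	358.8	282.5	323.3	332.1	280.2
urobilin	590	999.7	732.3	733.1	232.3	159.9	322.2	502.4
nicotinuric_acid	488.4	807.3	666.9	743.8	349.2	418.4	519.9	876.9
p-cresol	983.9	555.6	462.4	332.4	337.4	999.6	716.8	300.9
pyroglutamic_acid	236.3	321.9	608.1	630.5	263.5	480.5	205.3	627.8
taurine	276.9	496.3	353	402.5	446.3	240.3	521	442.9
succinate	413	476.2	323.9	289.5	404.3	434.1	524.6	489.8
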