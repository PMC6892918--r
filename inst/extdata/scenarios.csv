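label,timeframe,delta_t,delta_rad,co2
baseline,baseline,0,0,360
RCP2.6-GISS-ES-2030,2030,0.8,0.01,429
RCP2.6-HadGEM2-2030,2030,1.1,0.02,429
RCP8.5-GISS-ES-2030,2030,1.2,0.00,449
RCP8.5-HadGEM2-2030,2030,1.6,0.03,449
RCP2.6-GISS-ES-2050,2050,1.2,0.01,443
RCP2.6-HadGEM2-2050,2050,1.5,0.02,443
RCP8.5-GISS-ES-2050,2050,2.2,0.00,541
RCP8.5-HadGEM2-2050,2050,2.8,0.03,541
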