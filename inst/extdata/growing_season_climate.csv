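grassland,year,mean_temp,precip_mm,period_days,year_days
AMQH,2014,5.02,323.50,123,365
AMQH,2013,8.18,267.80,123,365
TSQH,2014,8.23,260.29,123,365
TSQH,2013,10.28,154.94,123,365
TSIM,2012,13.35,278.20,122,366
TSIM,2014,13.83,203.40,122,365
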