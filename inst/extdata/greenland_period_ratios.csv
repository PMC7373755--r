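# Published diagnostic-ratio values per sampling period for the same
# Greenland herbarium moss survey (value based on period average
# concentrations; min/max over per-sample values; NA = not computable
# in that period). Rule names match extdata/diagnostic_ratios.yaml.
rule,period,value,min,max
Fluoranthene/(Fluoranthene + Pyrene),1920s,0.59,0.56,0.61
Fluoranthene/(Fluoranthene + Pyrene),1940s,0.59,0.55,0.61
Fluoranthene/(Fluoranthene + Pyrene),1950s,0.60,0.56,0.63
Fluoranthene/(Fluoranthene + Pyrene),1960s,0.60,0.57,0.63
Fluoranthene/(Fluoranthene + Pyrene),1970s,0.58,0.56,0.62
Benz[a]anthracene/(Benz[a]anthracene + Chrysene),1920s,0.19,0.19,0.20
Benz[a]anthracene/(Benz[a]anthracene + Chrysene),1940s,NA,NA,NA
Benz[a]anthracene/(Benz[a]anthracene + Chrysene),1950s,0.29,0.28,0.30
Benz[a]anthracene/(Benz[a]anthracene + Chrysene),1960s,NA,NA,NA
Benz[a]anthracene/(Benz[a]anthracene + Chrysene),1970s,NA,NA,NA
Fluoranthene/Pyrene,1920s,1.44,1.28,1.59
Fluoranthene/Pyrene,1940s,1.40,1.22,1.61
Fluoranthene/Pyrene,1950s,1.43,1.29,1.67
Fluoranthene/Pyrene,1960s,1.52,1.30,1.70
Fluoranthene/Pyrene,1970s,1.41,1.29,1.64
HMW/LMW PAHs,1920s,0.10,0.05,0.14
HMW/LMW PAHs,1940s,0.09,0.03,0.80
HMW/LMW PAHs,1950s,0.17,0.03,0.71
HMW/LMW PAHs,1960s,0.10,0.07,0.18
HMW/LMW PAHs,1970s,0.11,0.06,0.78
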