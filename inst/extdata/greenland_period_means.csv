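# Published period summary of PAH concentrations (ng/g dry weight) in
# herbarium moss specimens from Greenland, 1920s-1970s (pooled across
# three species; the sole 1930s specimen is booked under the 1920s).
# mean is the conditional mean over above-LOQ values and is suppressed
# (NA) when fewer than two samples in the period detected the compound;
# min is NA where the printed range starts below LOQ.
# LMW/HMW/SigmaPAH rows are per-sample sums (censored = 0) averaged over
# all samples in the period.
period,compound,mean,min,max
1920s,naphthalene,370.6,163.9,484.9
1940s,naphthalene,304.1,NA,671.8
1950s,naphthalene,221.5,NA,417.2
1960s,naphthalene,116.5,NA,208.0
1970s,naphthalene,231.2,NA,379.2
1920s,phenanthrene,258.6,71.5,221.4
1940s,phenanthrene,134.6,NA,278.92
1950s,phenanthrene,127.7,NA,138.6
1960s,phenanthrene,286.6,NA,1252.9
1970s,phenanthrene,115.9,NA,221.4
1920s,fluoranthene,80.4,25.5,143.8
1940s,fluoranthene,47.2,12.7,98.4
1950s,fluoranthene,43.2,NA,165.5
1960s,fluoranthene,57.8,9.2,191.8
1970s,fluoranthene,36.2,9.2,95.3
1920s,pyrene,55.0,19.8,97.7
1940s,pyrene,33.7,9.2,71.8
1950s,pyrene,33.7,NA,114.7
1960s,pyrene,40.7,NA,112.9
1970s,pyrene,24.9,7.0,49.1
1920s,benz[a]anthracene,9.8,NA,10.2
1940s,benz[a]anthracene,13.1,NA,15.2
1950s,benz[a]anthracene,17.3,NA,20.8
1960s,benz[a]anthracene,6.3,NA,7.2
1970s,benz[a]anthracene,NA,NA,NA
1920s,chrysene,41.0,NA,44.8
1940s,chrysene,NA,NA,NA
1950s,chrysene,42.4,NA,49.5
1960s,chrysene,NA,NA,NA
1970s,chrysene,NA,NA,35.4
1920s,benzo[b]fluoranthene,NA,NA,NA
1940s,benzo[b]fluoranthene,NA,NA,NA
1950s,benzo[b]fluoranthene,NA,NA,46.3
1960s,benzo[b]fluoranthene,NA,NA,NA
1970s,benzo[b]fluoranthene,NA,NA,NA
1920s,benzo[k]fluoranthene,NA,NA,NA
1940s,benzo[k]fluoranthene,NA,NA,NA
1950s,benzo[k]fluoranthene,NA,NA,50.7
1960s,benzo[k]fluoranthene,NA,NA,NA
1970s,benzo[k]fluoranthene,NA,NA,NA
1920s,benzo[ghi]perylene,NA,NA,NA
1940s,benzo[ghi]perylene,NA,NA,18.9
1950s,benzo[ghi]perylene,NA,NA,37.2
1960s,benzo[ghi]perylene,NA,NA,NA
1970s,benzo[ghi]perylene,NA,NA,NA
1920s,LMW,709.6,351.8,1445.9
1940s,LMW,422.3,13.9,1073.1
1950s,LMW,314.9,17.7,772.8
1960s,LMW,390.0,65.2,1567.1
1970s,LMW,216.2,9.3,675.4
1920s,HMW,71.9,19.8,110.9
1940s,HMW,38.7,9.2,105.9
1950s,HMW,52.3,6.8,319.3
1960s,HMW,38.0,7.1,119.2
1970s,HMW,24.3,7.0,74.6
1920s,SigmaPAH,781.6,387.8,1590.3
1940s,SigmaPAH,461.0,25.3,1176.5
1950s,SigmaPAH,367.3,30.1,1092.1
1960s,SigmaPAH,428.0,72.3,1686.3
1970s,SigmaPAH,240.5,16.2,724.6
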