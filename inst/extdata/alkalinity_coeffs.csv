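term,value,note
intercept,2305,"Lee et al. (2006) subtropical-zone fit; external reference values"
s1,58.66,"coefficient on (SSS - s0)"
s2,2.32,"coefficient on (SSS - s0)^2"
t1,-1.41,"coefficient on (SST - t0)"
t2,0.04,"coefficient on (SST - t0)^2"
s0,35,"salinity centering (psu)"
t0,20,"temperature centering (deg C)"
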