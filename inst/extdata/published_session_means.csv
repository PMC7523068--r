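parameter,mean_test,sd_test,mean_retest,sd_retest,mdc95
TaskTime,58.95,31.73,53.82,31.16,57.94
MovementTime,3.20,0.74,2.97,0.77,2.58
PeakVel,28.32,9.97,27.61,9.29,12.06
HPR,1.91,0.39,1.79,0.36,1.28
nPeak,6.25,1.58,5.61,1.34,6.51
Score,70.66,36.81,73.46,36.90,32.84
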