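# Published box-plot summary of proteinoid microsphere diameters (nm):
# quartiles, mean, whisker endpoints (Tukey fences, 1.5*IQR) and the single
# flagged outlier, as printed with the diameter distribution figure.
statistic,value_nm
q1,1468.62
q2,1609.76
q3,1732.42
mean,1600.79
lower_whisker,1072.91
upper_whisker,2128.13
outlier,740.5680
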