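# Bit-exact transcription of the published per-academic-year screening
# classification counts (Nevada adolescent oral-health surveillance,
# 2002/2003 - 2007/2008).  Cells: tp = test-positive with disease,
# fp = test-positive without disease, fn = test-negative with disease,
# tn = test-negative without disease.  The printed_* columns are the row,
# column and grand totals exactly as printed; the 2004/2005 test-negative
# row total was printed as 4522 although its cells sum to 3112.
# Known print discrepancies in the published summary percentages relative
# to these cells: 2002/2003 predictive value negative printed 64 (cells
# give 62.78 -> 63); 2006/2007 prevalence printed 63 (cells give 62.46 -> 62).
year,tp,fp,fn,tn,printed_test_positive_total,printed_test_negative_total,printed_diseased_total,printed_nondiseased_total,printed_grand_total
2002/2003,4098,407,1366,2304,4505,3670,5464,2711,8175
2003/2004,6890,729,1722,2800,7619,4522,8612,3529,12141
2004/2005,3296,586,1041,2071,3882,4522,4337,2657,6994
2005/2006,4963,641,1090,2560,5604,3650,6053,3201,9254
2006/2007,3882,274,686,2471,4156,3157,4568,2745,7313
2007/2008,3842,667,1073,1836,4509,2909,4915,2503,7418
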