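site,species,ptt,n_relocations,start_date,end_date,days,dist_km,km_per_day
BAR,EG,7712202,2123,2008-10-23,2009-05-30,219,2491.18,11.38
BAR,EG,77127,6351,2008-06-07,2010-05-10,702,5587.85,7.96
BAR,EG,77128,3551,2008-06-22,2009-06-06,349,3041.57,8.72
BAR,EG,77128a,2551,2009-08-15,2010-05-25,283,3613.02,12.77
BAR,EG,77128b,1998,2010-09-25,2011-05-06,223,2882.35,12.93
BAR,EG,77128c,653,2011-07-31,2011-12-02,124,1159.43,9.35
BAR,EG,77129,3491,2008-06-07,2009-05-15,342,5265.88,15.40
BAR,EG,77130,2489,2008-11-09,2009-09-19,314,4645.91,14.80
BAR,EG,77130a,2140,2009-10-04,2010-06-04,243,3420.21,14.07
BAR,EG,77132,2601,2008-06-07,2009-05-30,357,3029.30,8.49
BAR,EG,77132a,2090,2009-08-13,2010-04-14,244,1744.40,7.15
BAR,RBT,77101,740,2008-04-09,2008-09-28,172,887.33,5.16
BAR,RBT,77102,4155,2008-04-10,2010-04-20,740,4161.22,5.62
BAR,RBT,77112,1843,2008-06-07,2009-05-15,342,1655.75,4.84
BAR,RBT,77115,1429,2008-10-11,2009-07-15,277,1616.16,5.83
JOZ,EG,7711702,1669,2012-05-04,2012-09-20,139,345.92,2.49
JOZ,EG,7712002,4317,2012-05-04,2013-05-24,385,5753.11,14.94
JOZ,EG,7712002a,2592,2013-06-09,2014-01-31,236,2806.24,11.89
JOZ,EG,7712102,1309,2012-05-05,2012-09-03,121,118.61,0.98
JOZ,EG,7713302,3009,2012-05-04,2013-02-19,291,975.21,3.35
MAN,EG,77125,6965,2008-05-07,2010-02-21,655,10997.20,16.79
MAN,EG,77125a,3689,2010-04-17,2011-05-31,409,5189.95,12.69
MAN,EG,77126,2682,2008-05-07,2008-12-26,233,2356.35,10.11
MAN,RBT,77103,610,2008-05-05,2008-08-24,111,1651.60,14.88
MAN,RBT,77104,1431,2008-05-05,2009-01-25,265,2366.17,8.93
MAN,RBT,77106,2587,2008-05-06,2009-07-25,445,2149.57,4.83
MAN,RBT,77108,644,2008-05-06,2008-08-29,115,711.25,6.18
MAN,RBT,77109,1307,2008-05-07,2008-12-24,231,1253.39,5.43
STR,EG,77094,1218,2008-01-12,2008-05-09,118,537.20,4.55
STR,EG,77094a,2686,2008-08-20,2009-05-01,254,1038.44,4.09
STR,EG,77095,3397,2008-01-12,2009-01-03,357,1798.93,5.04
STR,EG,7711802,6453,2009-01-17,2010-10-11,632,4201.96,6.65
STR,EG,7712302,1756,2008-12-05,2009-06-02,179,543.54,3.04
STR,EG,7713301,1506,2008-12-04,2009-04-27,144,1082.52,7.52
STR,EG,77134,5330,2008-12-01,2010-07-29,605,1893.01,3.13
STR,EG,77134a,2561,2010-08-19,2011-05-02,256,1144.43,4.47
STR,EG,77134b,2401,2011-07-22,2012-04-12,265,881.83,3.33
STR,EG,77135,8522,2008-12-01,2011-02-08,799,5155.63,6.45
STR,RBT,77092,1804,2008-03-12,2009-03-26,379,2217.02,5.85
STR,RBT,77093,993,2008-03-12,2008-09-07,179,611.10,3.41
STR,RBT,77098,3550,2008-03-14,2009-11-24,620,2173.40,3.51
STR,RBT,77099,1859,2008-03-14,2009-05-15,427,1532.42,3.59
STR,RBT,77100,2046,2008-03-14,2009-04-16,398,1445.63,3.63
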