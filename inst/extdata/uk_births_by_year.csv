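year,primary_care_caesarean,primary_care_vaginal,hes_caesarean,hes_vaginal,hes_known_policy_caesarean,hes_known_policy_vaginal
2005,NA,NA,98209,313235,47996,152839
2006,12326,34115,135839,422260,67733,210919
2007,12868,35094,138606,421346,69263,214954
2008,13232,36365,146365,447045,71086,220393
2009,13229,36264,150427,455737,75608,232258
2010,13504,36932,157367,474019,84371,255288
2011,13538,36389,157196,475408,89557,270032
2012,13772,35785,159710,471507,94338,279465
2013,12823,32089,154794,449047,91822,265662
2014,11783,28360,156090,439405,93579,263055
2015,9946,22945,159297,435153,95433,260729
2016,8407,18272,161659,429282,97564,257789
2017,7184,14798,38240,100641,23248,60370
2018,2249,3676,NA,NA,NA,NA
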