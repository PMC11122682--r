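# seed: 1
# config_hash: b8857d87cc94a1f13870fc796668375a
locality,year,host,n_striped,n_green,n_melanic
L01,2000,Adenostoma,2,15,1
L01,2000,Ceanothus,12,38,2
L01,2001,Adenostoma,6,10,0
L01,2001,Ceanothus,4,44,6
L01,2002,Adenostoma,4,12,0
L01,2002,Ceanothus,10,38,6
L01,2003,Adenostoma,2,15,1
L01,2003,Ceanothus,9,41,2
L01,2004,Adenostoma,3,19,3
L01,2004,Ceanothus,17,26,2
L01,2005,Adenostoma,4,11,2
L01,2005,Ceanothus,14,34,5
L01,2006,Adenostoma,7,12,1
L01,2006,Ceanothus,10,38,2
L01,2007,Adenostoma,6,8,1
L01,2007,Ceanothus,17,35,3
L01,2008,Adenostoma,8,15,3
L01,2008,Ceanothus,9,35,0
L01,2009,Adenostoma,6,12,1
L01,2009,Ceanothus,12,37,2
L01,2010,Adenostoma,4,11,2
L01,2010,Ceanothus,17,33,3
L01,2011,Adenostoma,3,11,1
L01,2011,Ceanothus,11,43,1
L01,2012,Adenostoma,2,10,0
L01,2012,Ceanothus,13,41,4
L01,2013,Adenostoma,0,14,0
L01,2013,Ceanothus,15,40,1
L02,2000,Adenostoma,5,15,1
L02,2000,Ceanothus,13,33,3
L02,2001,Adenostoma,7,21,1
L02,2001,Ceanothus,11,30,0
L02,2002,Adenostoma,7,18,1
L02,2002,Ceanothus,11,32,1
L02,2003,Adenostoma,6,20,0
L02,2003,Ceanothus,11,29,4
L02,2004,Adenostoma,6,13,0
L02,2004,Ceanothus,15,29,7
L02,2005,Adenostoma,4,18,1
L02,2005,Ceanothus,11,36,0
L02,2006,Adenostoma,3,16,2
L02,2006,Ceanothus,10,36,3
L02,2007,Adenostoma,5,11,1
L02,2007,Ceanothus,10,37,6
L02,2008,Adenostoma,10,12,0
L02,2008,Ceanothus,11,32,5
L02,2009,Adenostoma,8,11,0
L02,2009,Ceanothus,25,24,2
L02,2010,Adenostoma,6,13,1
L02,2010,Ceanothus,16,31,3
L02,2011,Adenostoma,3,21,1
L02,2011,Ceanothus,11,28,6
L02,2012,Adenostoma,5,14,2
L02,2012,Ceanothus,13,31,5
L02,2013,Adenostoma,4,13,0
L02,2013,Ceanothus,17,33,3
L03,2000,Adenostoma,13,19,4
L03,2000,Ceanothus,12,18,4
L03,2001,Adenostoma,9,15,1
L03,2001,Ceanothus,14,30,1
L03,2002,Adenostoma,4,17,0
L03,2002,Ceanothus,12,34,3
L03,2003,Adenostoma,5,18,4
L03,2003,Ceanothus,10,32,1
L03,2004,Adenostoma,10,17,0
L03,2004,Ceanothus,11,31,1
L03,2005,Adenostoma,11,17,0
L03,2005,Ceanothus,21,18,3
L03,2006,Adenostoma,9,15,2
L03,2006,Ceanothus,12,31,1
L03,2007,Adenostoma,10,18,1
L03,2007,Ceanothus,11,29,1
L03,2008,Adenostoma,6,15,1
L03,2008,Ceanothus,20,25,3
L03,2009,Adenostoma,8,17,2
L03,2009,Ceanothus,11,27,5
L03,2010,Adenostoma,14,13,4
L03,2010,Ceanothus,18,17,4
L03,2011,Adenostoma,9,23,0
L03,2011,Ceanothus,16,20,2
L03,2012,Adenostoma,11,12,1
L03,2012,Ceanothus,19,24,3
L03,2013,Adenostoma,9,15,0
L03,2013,Ceanothus,13,30,3
L04,2000,Adenostoma,16,19,1
L04,2000,Ceanothus,20,13,1
L04,2001,Adenostoma,11,12,2
L04,2001,Ceanothus,30,11,4
L04,2002,Adenostoma,18,15,3
L04,2002,Ceanothus,18,15,1
L04,2003,Adenostoma,14,23,1
L04,2003,Ceanothus,14,17,1
L04,2004,Adenostoma,10,26,1
L04,2004,Ceanothus,17,14,2
L04,2005,Adenostoma,17,15,1
L04,2005,Ceanothus,18,16,3
L04,2006,Adenostoma,16,9,0
L04,2006,Ceanothus,19,23,3
L04,2007,Adenostoma,9,17,6
L04,2007,Ceanothus,14,23,1
L04,2008,Adenostoma,11,17,1
L04,2008,Ceanothus,12,26,3
L04,2009,Adenostoma,15,14,1
L04,2009,Ceanothus,13,25,2
L04,2010,Adenostoma,14,13,1
L04,2010,Ceanothus,13,29,0
L04,2011,Adenostoma,11,18,2
L04,2011,Ceanothus,15,24,0
L04,2012,Adenostoma,8,17,3
L04,2012,Ceanothus,16,23,3
L04,2013,Adenostoma,12,15,0
L04,2013,Ceanothus,16,24,3
L05,2000,Adenostoma,12,21,1
L05,2000,Ceanothus,15,18,3
L05,2001,Adenostoma,20,19,3
L05,2001,Ceanothus,11,16,1
L05,2002,Adenostoma,11,27,2
L05,2002,Ceanothus,11,18,1
L05,2003,Adenostoma,17,21,0
L05,2003,Ceanothus,14,16,2
L05,2004,Adenostoma,11,25,1
L05,2004,Ceanothus,12,19,2
L05,2005,Adenostoma,12,16,2
L05,2005,Ceanothus,18,20,2
L05,2006,Adenostoma,18,17,0
L05,2006,Ceanothus,13,21,1
L05,2007,Adenostoma,14,23,2
L05,2007,Ceanothus,12,16,3
L05,2008,Adenostoma,18,16,2
L05,2008,Ceanothus,19,15,0
L05,2009,Adenostoma,12,20,0
L05,2009,Ceanothus,14,20,4
L05,2010,Adenostoma,17,18,1
L05,2010,Ceanothus,16,17,1
L05,2011,Adenostoma,16,17,0
L05,2011,Ceanothus,20,14,3
L05,2012,Adenostoma,21,13,1
L05,2012,Ceanothus,21,11,3
L05,2013,Adenostoma,22,18,1
L05,2013,Ceanothus,21,7,1
L06,2000,Adenostoma,12,24,2
L06,2000,Ceanothus,16,15,1
L06,2001,Adenostoma,24,11,3
L06,2001,Ceanothus,15,15,2
L06,2002,Adenostoma,23,18,1
L06,2002,Ceanothus,16,11,1
L06,2003,Adenostoma,24,16,2
L06,2003,Ceanothus,19,5,4
L06,2004,Adenostoma,19,23,0
L06,2004,Ceanothus,11,15,2
L06,2005,Adenostoma,15,26,2
L06,2005,Ceanothus,10,17,0
L06,2006,Adenostoma,20,18,2
L06,2006,Ceanothus,19,11,0
L06,2007,Adenostoma,25,10,3
L06,2007,Ceanothus,16,15,1
L06,2008,Adenostoma,17,19,3
L06,2008,Ceanothus,18,12,1
L06,2009,Adenostoma,22,20,3
L06,2009,Ceanothus,8,14,3
L06,2010,Adenostoma,15,14,2
L06,2010,Ceanothus,20,17,2
L06,2011,Adenostoma,25,9,1
L06,2011,Ceanothus,21,12,2
L06,2012,Adenostoma,28,13,2
L06,2012,Ceanothus,17,7,3
L06,2013,Adenostoma,27,11,0
L06,2013,Ceanothus,22,10,0
L07,2000,Adenostoma,40,11,1
L07,2000,Ceanothus,12,6,0
L07,2001,Adenostoma,26,10,2
L07,2001,Ceanothus,21,9,2
L07,2002,Adenostoma,28,15,0
L07,2002,Ceanothus,19,7,1
L07,2003,Adenostoma,26,20,0
L07,2003,Ceanothus,17,7,0
L07,2004,Adenostoma,35,8,1
L07,2004,Ceanothus,16,9,1
L07,2005,Adenostoma,34,11,4
L07,2005,Ceanothus,18,2,1
L07,2006,Adenostoma,29,14,2
L07,2006,Ceanothus,15,7,3
L07,2007,Adenostoma,30,14,2
L07,2007,Ceanothus,17,7,0
L07,2008,Adenostoma,23,17,1
L07,2008,Ceanothus,19,9,1
L07,2009,Adenostoma,33,13,2
L07,2009,Ceanothus,14,8,0
L07,2010,Adenostoma,25,20,1
L07,2010,Ceanothus,11,13,0
L07,2011,Adenostoma,29,11,1
L07,2011,Ceanothus,18,11,0
L07,2012,Adenostoma,22,18,2
L07,2012,Ceanothus,15,13,0
L07,2013,Adenostoma,18,26,1
L07,2013,Ceanothus,16,9,0
L08,2000,Adenostoma,32,16,2
L08,2000,Ceanothus,15,4,1
L08,2001,Adenostoma,35,18,2
L08,2001,Ceanothus,12,1,2
L08,2002,Adenostoma,38,8,3
L08,2002,Ceanothus,16,4,1
L08,2003,Adenostoma,37,16,3
L08,2003,Ceanothus,9,5,0
L08,2004,Adenostoma,40,9,1
L08,2004,Ceanothus,11,7,2
L08,2005,Adenostoma,31,10,5
L08,2005,Ceanothus,18,4,2
L08,2006,Adenostoma,33,10,3
L08,2006,Ceanothus,18,5,1
L08,2007,Adenostoma,35,20,1
L08,2007,Ceanothus,10,3,1
L08,2008,Adenostoma,40,8,3
L08,2008,Ceanothus,16,3,0
L08,2009,Adenostoma,26,19,3
L08,2009,Ceanothus,16,6,0
L08,2010,Adenostoma,31,17,4
L08,2010,Ceanothus,10,6,2
L08,2011,Adenostoma,34,18,1
L08,2011,Ceanothus,10,6,1
L08,2012,Adenostoma,24,19,2
L08,2012,Ceanothus,16,9,0
L08,2013,Adenostoma,38,15,1
L08,2013,Ceanothus,14,1,1
L09,2000,Adenostoma,37,17,3
L09,2000,Ceanothus,9,3,1
L09,2001,Adenostoma,42,7,4
L09,2001,Ceanothus,10,5,2
L09,2002,Adenostoma,38,10,8
L09,2002,Ceanothus,10,4,0
L09,2003,Adenostoma,42,11,1
L09,2003,Ceanothus,11,4,1
L09,2004,Adenostoma,35,17,0
L09,2004,Ceanothus,15,3,0
L09,2005,Adenostoma,44,15,2
L09,2005,Ceanothus,8,1,0
L09,2006,Adenostoma,47,11,1
L09,2006,Ceanothus,9,2,0
L09,2007,Adenostoma,41,10,3
L09,2007,Ceanothus,12,4,0
L09,2008,Adenostoma,51,7,0
L09,2008,Ceanothus,6,5,1
L09,2009,Adenostoma,53,4,0
L09,2009,Ceanothus,9,2,2
L09,2010,Adenostoma,36,12,4
L09,2010,Ceanothus,13,5,0
L09,2011,Adenostoma,31,15,2
L09,2011,Ceanothus,14,7,1
L09,2012,Adenostoma,42,9,7
L09,2012,Ceanothus,8,4,0
L09,2013,Adenostoma,48,2,2
L09,2013,Ceanothus,15,2,1
L10,2000,Adenostoma,50,10,3
L10,2000,Ceanothus,4,2,1
L10,2001,Adenostoma,48,7,5
L10,2001,Ceanothus,9,0,1
L10,2002,Adenostoma,54,4,0
L10,2002,Ceanothus,10,2,0
L10,2003,Adenostoma,47,10,3
L10,2003,Ceanothus,8,1,1
L10,2004,Adenostoma,52,12,2
L10,2004,Ceanothus,2,1,1
L10,2005,Adenostoma,46,9,2
L10,2005,Ceanothus,8,2,3
L10,2006,Adenostoma,48,9,5
L10,2006,Ceanothus,8,0,0
L10,2007,Adenostoma,53,4,2
L10,2007,Ceanothus,11,0,0
L10,2008,Adenostoma,49,9,2
L10,2008,Ceanothus,10,0,0
L10,2009,Adenostoma,47,6,3
L10,2009,Ceanothus,11,2,1
L10,2010,Adenostoma,53,7,3
L10,2010,Ceanothus,6,1,0
L10,2011,Adenostoma,43,14,3
L10,2011,Ceanothus,5,5,0
L10,2012,Adenostoma,45,14,1
L10,2012,Ceanothus,10,0,0
L10,2013,Adenostoma,45,10,6
L10,2013,Ceanothus,7,2,0
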