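child_id,age_y,weight_kg,height_cm,ttma_mg_L,below_loq,creatinine_g_L,acr_mg_g,acr_normal
T01,6,25,113,0.005,TRUE,0.8,12,TRUE
T02,7,28,119,0.199,FALSE,1,12,TRUE
T03,8,31,125,0.0073,TRUE,1.2,12,TRUE
T04,9,34,131,0.0095,TRUE,0.8,12,TRUE
T05,10,37,137,0.35,FALSE,1,48,FALSE
T06,11,40,143,0.0118,TRUE,1.2,12,TRUE
T07,12,43,149,0.217,FALSE,0.8,12,TRUE
T08,6,25,113,0.0141,TRUE,1,12,TRUE
T09,7,28,119,0.0164,TRUE,1.2,12,TRUE
T10,8,31,125,0.2349,FALSE,0.8,12,TRUE
T11,9,34,131,0.0186,TRUE,1,12,TRUE
T12,10,37,137,0.2617,FALSE,1.2,12,TRUE
T13,11,40,143,0.0209,TRUE,0.8,12,TRUE
T14,12,43,149,0.0232,TRUE,1,12,TRUE
T15,6,25,113,0.2886,FALSE,1.2,12,TRUE
T16,7,28,119,0.0255,TRUE,0.8,12,TRUE
T17,8,31,125,0.3245,FALSE,1,12,TRUE
T18,9,34,131,0.0277,TRUE,1.2,12,TRUE
T19,10,37,137,0.03,TRUE,0.8,12,TRUE
T20,11,40,143,0.92,FALSE,1,85,FALSE
T21,12,43,149,0.0323,TRUE,1.2,12,TRUE
T22,6,25,113,0.3782,FALSE,0.8,12,TRUE
T23,7,28,119,0.0345,TRUE,1,12,TRUE
T24,8,31,125,0.0368,TRUE,1.2,12,TRUE
T25,9,34,131,0.4409,FALSE,0.8,12,TRUE
T26,10,37,137,0.0391,TRUE,1,12,TRUE
T27,11,40,143,0.5305,FALSE,1.2,12,TRUE
T28,12,43,149,0.0414,TRUE,0.8,12,TRUE
T29,6,25,113,0.0436,TRUE,1,12,TRUE
T30,7,28,119,0.6649,FALSE,1.2,12,TRUE
T31,8,31,125,0.0459,TRUE,0.8,12,TRUE
T32,9,34,131,0.844,FALSE,1,12,TRUE
T33,10,37,137,0.0482,TRUE,1.2,12,TRUE
T34,11,40,143,0.0505,TRUE,0.8,12,TRUE
T35,12,43,149,1.6,FALSE,1,132,FALSE
T36,6,25,113,0.0527,TRUE,1.2,12,TRUE
T37,7,28,119,1.1128,FALSE,0.8,12,TRUE
T38,8,31,125,0.055,TRUE,1,12,TRUE
T39,9,34,131,1.4711,FALSE,1.2,12,TRUE
T40,10,37,137,2.0982,FALSE,0.8,12,TRUE
T41,11,40,143,3.0836,FALSE,1,12,TRUE
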