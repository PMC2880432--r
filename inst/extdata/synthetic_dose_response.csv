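"cell_class","dose_gy","sa_bgal_negative_fraction"
"normal",0,1.03549602041548
"normal",0.5,0.808497466155417
"normal",1,0.714311562411042
"normal",2,0.440441427213865
"normal",4,0.207339651273193
"normal",6,0.0979878471839033
"variant",0,1.02407564416
"variant",0.5,1.00467844783741
"variant",1,1.03085305400203
"variant",2,0.921142912559335
"variant",4,0.978163628122331
"variant",6,0.887802405848007
"variant",10,0.76559192290812
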