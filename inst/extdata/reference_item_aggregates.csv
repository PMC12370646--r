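item,block,weighted_f1,acc0_pct,acc1_pct,kappa_w,macro_f1,n_features,n
3.9,loocv,0.748,74.4,99.4,0.52,0.626,35,180
3.10,loocv,0.786,78.3,98.9,0.64,0.695,35,180
3.11,loocv,0.828,81.7,87.2,0.53,0.6,30,180
3.12,loocv,0.571,56.7,80.6,0.51,0.481,30,180
3.13,loocv,0.6,59.4,88.3,0.5,0.572,40,180
3.9,test,0.767,77.8,100.0,0.573,0.783,35,45
3.10,test,0.715,71.1,100.0,0.539,0.679,35,45
3.11,test,0.777,82.2,93.3,0.664,0.823,30,45
3.12,test,0.408,40.0,66.7,0.278,0.422,30,45
3.13,test,0.463,46.7,84.4,0.308,0.397,40,45
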