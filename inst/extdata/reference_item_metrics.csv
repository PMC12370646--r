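item,block,class_label,precision,recall,f1,support
3.9,loocv,0,0.855,0.803,0.828,117
3.9,loocv,1,0.587,0.661,0.622,56
3.9,loocv,2/3/4,0.429,0.429,0.429,7
3.9,test,0,0.769,0.87,0.816,23
3.9,test,1,0.789,0.714,0.75,21
3.9,test,2/3/4,NA,0,NA,1
3.10,loocv,0,0.5,0.462,0.48,13
3.10,loocv,1,0.694,0.843,0.761,70
3.10,loocv,2/3,0.916,0.784,0.844,97
3.10,test,0,0.75,0.75,0.75,4
3.10,test,1,0.462,0.5,0.48,12
3.10,test,2/3,0.821,0.793,0.807,29
3.11,loocv,0,0.932,0.849,0.889,146
3.11,loocv,1,0.25,0.333,0.286,6
3.11,loocv,2/3/4,0.538,0.75,0.627,28
3.11,test,0,0.882,0.938,0.909,32
3.11,test,1,NA,0,NA,5
3.11,test,2/3/4,0.636,0.875,0.737,8
3.12,loocv,0,0.667,0.712,0.689,59
3.12,loocv,1,0.614,0.474,0.535,57
3.12,loocv,2,0.2,0.3,0.24,10
3.12,loocv,3,0.578,0.578,0.578,45
3.12,loocv,4,0.308,0.444,0.364,9
3.12,test,0,0.562,0.6,0.581,15
3.12,test,1,0.273,0.3,0.286,10
3.12,test,2,0,0,NA,2
3.12,test,3,0.462,0.353,0.4,17
3.12,test,4,0,0,NA,1
3.13,loocv,0,0.66,0.714,0.686,49
3.13,loocv,1,0.726,0.562,0.634,80
3.13,loocv,2,0.375,0.455,0.411,33
3.13,loocv,3/4,0.48,0.667,0.558,18
3.13,test,0,0.5,0.571,0.533,14
3.13,test,1,0.526,0.526,0.526,19
3.13,test,2,0.4,0.25,0.308,8
3.13,test,3/4,0.2,0.25,0.222,4
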