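method,mode,accuracy,error_rate,f1,iou,precision,recall,specificity
sam,local,0.8544,14.56,0.1666,0.0909,0.0931,0.7957,0.8555
sam,simultaneous,0.8197,18.03,0.1572,0.0853,0.0859,0.9185,0.8179
sam,sequential,0.9869,1.31,0.5785,0.4069,0.4801,0.7275,0.9901
rf,local,0.9957,0.43,0.8736,0.7755,0.9334,0.8210,0.9989
rf,simultaneous,0.9965,0.35,0.8996,0.8176,0.9522,0.8525,0.9992
rf,sequential,0.9971,0.29,0.8808,0.7870,0.9134,0.8505,0.9990
svm,local,0.9960,0.0040,0.8842,0.7924,0.9299,0.8428,0.9988
svm,simultaneous,0.9957,0.0043,0.8734,0.7753,0.9392,0.8162,0.9990
svm,sequential,0.9966,0.0034,0.8597,0.7539,0.8774,0.8427,0.9985
nn,local,0.9953,0.0047,0.8616,0.7568,0.9328,0.8004,0.9989
nn,simultaneous,0.9952,0.0048,0.8625,0.7582,0.9152,0.8155,0.9986
nn,sequential,0.9962,0.0038,0.8356,0.7176,0.9012,0.7788,0.9989
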