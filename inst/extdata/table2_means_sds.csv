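variable,mean,sd,min,max
dvc_tracking,89.6,5.6,72,98
dvc_sudden,92.9,5.4,76,99
dsp_p1,5.8,1.5,3,9
dsp_p2,11.1,1,7,12
dsp_p3,2.5,1.2,2,6
dsp_p4,4.9,1.4,2,6
dsp_p5,4.5,1.1,2,6
dsp_p6,9.6,1.6,4,12
dsp_total,38.3,4.8,26,51
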