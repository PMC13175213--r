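arm,mean_f1,std_f1,mean_accuracy,std_accuracy
NIH-only,0.747,0.024,0.754,0.022
UCL-only,0.582,0.037,0.567,0.038
federated,0.820,0.032,0.825,0.031
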