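scenario,strategy,cost,yield
base,2nd-line ES,1402,0.421
base,Standard genetic testing,2429,0.282
base,Last-resort ES,3168,0.448
base,2nd-line GS,5194,0.447
base,1st-line GS,5576,0.460
base,Last-resort GS,6112,0.461
low_gs,2nd-line ES,1402,0.421
low_gs,Standard genetic testing,2429,0.282
low_gs,Last-resort ES,3168,0.448
low_gs,2nd-line GS,3657,0.447
low_gs,1st-line GS,3781,0.460
low_gs,Last-resort GS,4933,0.461
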