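metric,oobtr_or,model_or,model_oobtr
mae,0.4560,0.3305,0.4316
precision,61.63,68.31,71.18
recall,62.05,67.12,68.70
f1,61.38,66.99,69.05
r_squared,0.55,0.614,0.6769
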