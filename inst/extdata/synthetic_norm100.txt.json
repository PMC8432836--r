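{"model":"normal","params":{"mean":0,"sd":1},"theta":1,"n":100,"seed":106}
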