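{"name": "DemoSeq", "pos": [[0,0], [2,3], [3,0]], "light": [[255,0,0,0], [0,255,0,0], [0,0,255,0]], "delay": [30,60,0], "sampling": true, "volume": [1,2,3], "trash": true, "capture": true}
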