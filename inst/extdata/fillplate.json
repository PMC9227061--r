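{"name": "Fill plate 1","pos":[[0,0],[1,0],[2,0],[0,1],[1,1],[2,1],[0,2],[1,2],[2,2],[0,3],[1,3],[2,3]],"sampling": true,"volume": [1]}
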