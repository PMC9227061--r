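{"name":"MaxThroughput","pos":[[0,0],[1,0],[2,0],[0,1],[1,1],[2,1],[0,2],[1,2],[2,2],[0,3],[1,3],[2,3],[3,0],[4,0],[5,0],[3,1],[4,1],[5,1],[3,2],[4,2],[5,2],[3,3],[4,3],[5,3]],"light": [[0,0,0,255]], "delay": [0], "sampling": true, "volume": [1], "trash": false, "capture": true}
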