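# Synthetic four-simplex, seven-vertex illustration of q-nearness:
# two 3-simplices sharing the 2-face {V1, V5, V6}, a 2-simplex meeting
# the first in {V6} and the second in {V6, V7}, and a 1-simplex via V2.
V1 V4 V5 V6
V1 V5 V6 V7
V2 V6 V7
V2 V3
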