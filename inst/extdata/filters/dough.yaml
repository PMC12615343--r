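# Dough (carbohydrate-rich) segmentation rules, OpenCV HSV convention
# (H in 0-180 half-degree units, S and V in 0-255).
hue_convention: opencv
s_filter: "(H > 80 & H < 120) | S > 25"
c_filter: "H > 90 & S < 130 & V > 100"
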