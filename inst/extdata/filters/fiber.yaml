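# Fiber-rich ink segmentation rules -- PLACEHOLDER.
# Thresholds differ per ink class and camera setup; these start from the
# dough rules and must be tuned on the target dataset.
hue_convention: opencv
s_filter: "(H > 80 & H < 120) | S > 25"
c_filter: "H > 90 & S < 130 & V > 100"
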