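# Channel frequency-allocation boundary tables for the "device standard"
# edge mode. Keys are channel counts; values are the N+1 band-edge
# frequencies in Hz, low to high.
#
# The 22-channel table is the standard Cochlear Ltd. frequency allocation
# (FFT-bin-derived, 125 Hz analysis spacing), spanning 188-7938 Hz.
# Additional channel counts may be added by the user and loaded with
# `cochlear_edges(n, table = "path/to/your.yaml")`.
22: [188, 313, 438, 563, 688, 813, 938, 1063, 1188, 1313,
     1563, 1813, 2063, 2313, 2688, 3063, 3563, 4063, 4688,
     5313, 6063, 6938, 7938]
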