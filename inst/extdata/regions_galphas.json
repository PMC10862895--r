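{
  "switch1": [197, 198, 199, 200, 201, 202, 203, 204, 205, 206, 207],
  "switch2": [225, 226, 227, 228, 229, 230, 231, 232, 233, 234, 235],
  "switch3": [252, 253, 254, 255, 256, 257, 258, 259, 260, 261, 262, 263, 264, 265, 266, 267, 268]
}
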