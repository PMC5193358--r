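{
  "am": [-2.27e-04, -6.40e-05, 1.61e-04, 1.43e-03, 1.82e+03],
  "sl": [9.79e-01, 3.45e-02, 1.07e+00, -1.46e+00, -6.97e-03],
  "scales": {"mass": 100, "age": 100, "height": 10, "torque": 100},
  "provenance": "published-Table2"
}
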