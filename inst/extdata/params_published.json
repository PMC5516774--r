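{
  "k_S": 2.7938,
  "delta_D": 9.9626,
  "alpha_M": 0.0727,
  "k_D": 2,
  "delta_R": 0.0727,
  "s_C": 9.517,
  "alpha": 1.0001,
  "k_E": 0.0961,
  "lambda_E": 0.0418,
  "R_0": 0.99990000999900008,
  "epsilon": 1e-4,
  "delta_E": 2.2067988694576282,
  "k_U": 5.0,
  "lambda_U": 0.3387
}
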