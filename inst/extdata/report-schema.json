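{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "AVC method-agreement report",
  "type": "object",
  "required": ["n", "icc", "icc_ci_low", "icc_ci_high", "r2", "bias",
               "loa_lower", "loa_upper", "prop_bias_slope", "prop_bias_p",
               "icc_form", "difference_convention"],
  "properties": {
    "n": {"type": "number"},
    "icc": {"type": "number"},
    "icc_ci_low": {"type": "number"},
    "icc_ci_high": {"type": "number"},
    "icc_p_value": {"type": "number"},
    "icc_form": {"type": "string"},
    "r2": {"type": "number"},
    "bias": {"type": "number"},
    "loa_lower": {"type": "number"},
    "loa_upper": {"type": "number"},
    "prop_bias_slope": {"type": "number"},
    "prop_bias_p": {"type": "number"},
    "difference_convention": {"type": "string"},
    "model": {"type": "object"}
  }
}
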