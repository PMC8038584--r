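{
  "t1_01": {
    "source": "literature comparison, case 1",
    "expected": {
      "physiological": ["hagma", "metabolic_alkalosis"],
      "chemical": ["hagma", "metabolic_alkalosis"]
    }
  },
  "t1_02": {
    "source": "literature comparison, case 2",
    "expected": {
      "physiological": ["hagma", "metabolic_alkalosis"],
      "chemical": ["hagma", "metabolic_alkalosis"]
    }
  },
  "t1_03": {
    "source": "literature comparison, case 3",
    "expected": {
      "physiological": ["respiratory_alkalosis", "hagma", "metabolic_alkalosis|none|probable"],
      "chemical": ["respiratory_alkalosis", "hagma", "metabolic_alkalosis|none|probable"]
    }
  },
  "t1_04": {
    "source": "literature comparison, case 4",
    "expected": {
      "physiological": ["hagma", "respiratory_acidosis", "metabolic_alkalosis|none|probable"],
      "chemical": ["hagma", "respiratory_acidosis", "metabolic_alkalosis|none|probable"]
    }
  },
  "t1_05": {
    "source": "literature comparison, case 5",
    "expected": {
      "physiological": ["metabolic_alkalosis", "respiratory_alkalosis"],
      "chemical": ["metabolic_alkalosis", "respiratory_alkalosis"]
    }
  },
  "t1_06": {
    "source": "literature comparison, case 6",
    "expected": {
      "physiological": ["respiratory_acidosis", "metabolic_alkalosis"],
      "chemical": ["respiratory_acidosis", "metabolic_alkalosis"]
    }
  },
  "t1_07": {
    "source": "literature comparison, case 7",
    "expected": {
      "physiological": ["respiratory_alkalosis|chronic", "hagma", "metabolic_alkalosis"],
      "chemical": ["respiratory_alkalosis|chronic", "hagma", "metabolic_alkalosis"]
    }
  },
  "t1_08": {
    "source": "literature comparison, case 8",
    "expected": {
      "physiological": ["hagma", "respiratory_acidosis", "metabolic_alkalosis|none|probable"],
      "chemical": ["hagma", "respiratory_acidosis", "metabolic_alkalosis|none|probable"]
    }
  },
  "t1_09": {
    "source": "literature comparison, case 9",
    "expected": {
      "physiological": ["nagma", "respiratory_acidosis"],
      "physiological_agc": ["hagma", "respiratory_acidosis", "nagma|none|probable"],
      "chemical": ["nagma", "respiratory_acidosis"],
      "chemical_agc": ["hagma", "respiratory_acidosis", "nagma|none|probable"]
    }
  },
  "t2_01": {
    "source": "survey case 1",
    "expected": {
      "physiological": ["respiratory_alkalosis", "hagma"]
    }
  },
  "t2_02": {
    "source": "survey case 2",
    "expected": {
      "physiological": ["hagma", "metabolic_alkalosis"]
    }
  },
  "t2_03": {
    "source": "survey case 3",
    "expected": {
      "physiological": ["respiratory_alkalosis", "hagma", "metabolic_alkalosis"]
    }
  },
  "t2_04": {
    "source": "survey case 4",
    "expected": {
      "physiological": ["respiratory_acidosis", "hagma", "metabolic_alkalosis"]
    }
  },
  "t2_05": {
    "source": "survey case 5 (very low albumin; corrected-gap approach is decisive)",
    "expected": {
      "physiological_agc": ["hagma"]
    }
  },
  "t2_06": {
    "source": "survey case 6",
    "reject": true,
    "expected": {}
  },
  "t2_07": {
    "source": "survey case 7",
    "expected": {
      "physiological": ["respiratory_alkalosis", "metabolic_alkalosis"]
    }
  },
  "t2_08": {
    "source": "survey case 8",
    "expected": {
      "physiological": ["respiratory_alkalosis|acute"]
    }
  },
  "t2_09": {
    "source": "survey case 9",
    "expected": {
      "physiological": ["respiratory_acidosis", "nagma"]
    }
  },
  "t2_10": {
    "source": "survey case 10",
    "expected": {
      "physiological": ["respiratory_acidosis|acute"]
    }
  },
  "ex1": {
    "source": "worked example 1 (fully normal panel)",
    "compliance": 100,
    "expected": {
      "physiological": [],
      "physiological_agc": [],
      "chemical": [],
      "chemical_agc": []
    }
  },
  "ex2": {
    "source": "worked example 2 (metabolic alkalosis with inadequate CO2 retention)",
    "compliance": 100,
    "expected": {
      "physiological": ["metabolic_alkalosis", "respiratory_alkalosis"],
      "chemical": ["metabolic_alkalosis", "respiratory_alkalosis"]
    }
  },
  "ex3": {
    "source": "worked example 3 (hypoalbuminaemia masking a high anion gap)",
    "compliance": 50,
    "expected": {
      "physiological": ["nagma", "respiratory_acidosis"],
      "physiological_agc": ["hagma", "respiratory_acidosis", "nagma|none|probable"],
      "chemical": ["nagma", "respiratory_acidosis"],
      "chemical_agc": ["hagma", "respiratory_acidosis", "nagma|none|probable"]
    }
  },
  "d42_hagma": {
    "source": "application comparison: elevated gap at normal pH (AG from Na/Cl)",
    "compliance": 100,
    "expected": {
      "physiological": ["hagma", "metabolic_alkalosis"],
      "physiological_agc": ["hagma", "metabolic_alkalosis"],
      "chemical": ["hagma", "metabolic_alkalosis"],
      "chemical_agc": ["hagma", "metabolic_alkalosis"]
    }
  },
  "d42_normal": {
    "source": "application comparison: all values within reference ranges",
    "compliance": 100,
    "expected": {
      "physiological": [],
      "physiological_agc": [],
      "chemical": [],
      "chemical_agc": []
    }
  },
  "d43": {
    "source": "discordant-approaches case; the published chemical-approach certainty is not recoverable from the stated rules",
    "known_divergent": ["chemical", "chemical_agc"],
    "expected": {
      "physiological": ["hagma"],
      "physiological_agc": ["hagma", "metabolic_alkalosis|none|probable"]
    }
  }
}
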