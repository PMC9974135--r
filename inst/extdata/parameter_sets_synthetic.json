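{
  "metadata": {
    "description": "Synthetic default parameter sets for the exercise-extended glucose-insulin model. The structural constants fixed in the model definition (tau_AC, tau_Z, a_Y, n1, a_AC, n2, a_h, t_p, q5, q6) are shared across sets. All other numeric values are package defaults chosen from physiological ranges for a ~50 kg subject with type 1 diabetes; they are NOT measured constants. The three sets mirror the structure of clamp-condition variants: v1 = euglycemia / low insulin (standard), v2 = euglycemia / high insulin, v3 = hyperglycemia / low insulin.",
    "units": {
      "p1": "1/min", "p2": "1/min", "p3": "1/min^2 per uU/ml",
      "p4": "1/min", "p5": "1/min", "Vg": "dl/kg", "BW": "kg",
      "Gb": "mg/dl", "ub": "uU/min",
      "tau_AC": "min", "tau_Z": "min", "b": "1/count",
      "a_Y": "counts/min", "n1": "-", "a_AC": "counts/min", "n2": "-",
      "a_h": "counts/min", "t_p": "min", "q5": "1/min",
      "q1": "1/count", "q2": "1/min", "q3l": "1/count", "q4l": "1/min",
      "q3h": "1/count", "q4h": "1/min", "q6": "1/min",
      "a_depl": "min per counts/min", "b_depl": "min",
      "beta": "-", "alpha": "-",
      "k1": "1/min", "k2": "1/min", "k3": "1/min", "k4": "1/min",
      "VI": "ml/kg"
    }
  },
  "sets": {
    "v1": {
      "p1": 0.02, "p2": 0.025, "p3": 1.3e-05, "p4": 0.05, "p5": 0.05,
      "Vg": 1.6, "BW": 50, "Gb": 130, "ub": 13333.333333333334,
      "tau_AC": 5, "tau_Z": 600, "b": 2e-06,
      "a_Y": 1500, "n1": 20, "a_AC": 1000, "n2": 100,
      "a_h": 5600, "t_p": 2, "q5": 0.03,
      "q1": 2.3e-07, "q2": 0.05, "q3l": 1.15e-07, "q4l": 0.05,
      "q3h": 4.6e-07, "q4h": 0.05, "q6": 0.1,
      "a_depl": 0.036, "b_depl": 305,
      "beta": 0.8, "alpha": 0.6,
      "k1": 0.025, "k2": 0.018, "k3": 0.004, "k4": 0.15, "VI": 140
    },
    "v2": {
      "p1": 0.02, "p2": 0.025, "p3": 1.1e-05, "p4": 0.05, "p5": 0.05,
      "Vg": 1.6, "BW": 50, "Gb": 110, "ub": 20000,
      "tau_AC": 5, "tau_Z": 600, "b": 1.5e-06,
      "a_Y": 1500, "n1": 20, "a_AC": 1000, "n2": 100,
      "a_h": 5600, "t_p": 2, "q5": 0.03,
      "q1": 2.0e-07, "q2": 0.05, "q3l": 1.0e-07, "q4l": 0.05,
      "q3h": 4.0e-07, "q4h": 0.05, "q6": 0.1,
      "a_depl": 0.036, "b_depl": 305,
      "beta": 0.8, "alpha": 0.6,
      "k1": 0.025, "k2": 0.018, "k3": 0.004, "k4": 0.15, "VI": 140
    },
    "v3": {
      "p1": 0.018, "p2": 0.025, "p3": 1.0e-05, "p4": 0.05, "p5": 0.05,
      "Vg": 1.6, "BW": 50, "Gb": 180, "ub": 10000,
      "tau_AC": 5, "tau_Z": 600, "b": 2.2e-06,
      "a_Y": 1500, "n1": 20, "a_AC": 1000, "n2": 100,
      "a_h": 5600, "t_p": 2, "q5": 0.03,
      "q1": 2.6e-07, "q2": 0.05, "q3l": 1.3e-07, "q4l": 0.05,
      "q3h": 5.2e-07, "q4h": 0.05, "q6": 0.1,
      "a_depl": 0.036, "b_depl": 305,
      "beta": 0.8, "alpha": 0.6,
      "k1": 0.025, "k2": 0.018, "k3": 0.004, "k4": 0.15, "VI": 140
    }
  }
}
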