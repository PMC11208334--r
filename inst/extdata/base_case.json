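{
  "scenarios": {
    "no_psp": {
      "q_hie": 0.02,
      "p_dayoff_high": 0.050000000000000003,
      "p_dayoff_low": 0.002,
      "p_quit_high": 0.0067999999999999996,
      "p_quit_low": 0.00029999999999999997,
      "recovery_prob": 0.14285714285714285
    },
    "psp": {
      "q_hie": 0.02,
      "p_dayoff_high": 0.029999999999999999,
      "p_dayoff_low": 0.002,
      "p_quit_high": 0.0033999999999999998,
      "p_quit_low": 0.0001,
      "recovery_prob": 0.14285714285714285
    }
  },
  "costs": {
    "cost_per_sick_day": 500,
    "cost_per_quit": 75000,
    "psp_cost_per_person": 550,
    "currency": "EUR"
  },
  "cohort": {
    "n_staff": 1000,
    "horizon_days": 365,
    "initial_distribution": [1, 0, 0]
  }
}
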