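{
  "name": "smmterf33_preset_synthetic",
  "gene": "SmmTERF33",
  "comment": "Synthetic locus geometry: 27 phased 21-nt registers per strand downstream of a 22-nt trigger cleavage site; occupancy reflects that a minority of enumerated species go undetected. Sequences generated by simulatePhasiRNALocus() are synthetic.",
  "seed": 33,
  "period": 21,
  "triggerLength": 22,
  "transcriptLength": 780,
  "cleavagePosition": 200,
  "nRegisters": 27,
  "occupancy": 0.76,
  "readsPerRegister": 20,
  "abundanceSdlog": 0.8,
  "noiseFraction": 0.05,
  "degradomePeakFraction": 0.9,
  "backgroundRate": 0.2,
  "antisenseOffset": 2
}
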