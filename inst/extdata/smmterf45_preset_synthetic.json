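{
  "name": "smmterf45_preset_synthetic",
  "gene": "SmmTERF45",
  "comment": "Synthetic locus geometry: 28 phased 21-nt registers per strand downstream of a 22-nt trigger cleavage site. Sequences generated by simulatePhasiRNALocus() are synthetic.",
  "seed": 45,
  "period": 21,
  "triggerLength": 22,
  "transcriptLength": 800,
  "cleavagePosition": 200,
  "nRegisters": 28,
  "occupancy": 0.8,
  "readsPerRegister": 20,
  "abundanceSdlog": 0.8,
  "noiseFraction": 0.05,
  "degradomePeakFraction": 0.9,
  "backgroundRate": 0.2,
  "antisenseOffset": 2
}
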