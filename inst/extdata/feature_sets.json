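{
  "version": 1,
  "comment": "Pinned reduced feature-set manifests. The twelve wavelet members draw on the prefrontal electrodes, the haar mother wavelet, detail coefficients cD1/cD7/cD8 and the statistics Kurtosis, Mean and ZeroCrossing.",
  "dwt_twelve": [
    "AF7_haar_cD1_Kurtosis", "AF7_haar_cD1_ZeroCrossing",
    "AF7_haar_cD7_MEAN", "AF7_haar_cD7_ZeroCrossing",
    "AF7_haar_cD8_Kurtosis", "AF7_haar_cD8_MEAN",
    "AF8_haar_cD1_Kurtosis", "AF8_haar_cD1_ZeroCrossing",
    "AF8_haar_cD7_MEAN", "AF8_haar_cD7_ZeroCrossing",
    "AF8_haar_cD8_Kurtosis", "AF8_haar_cD8_MEAN"
  ],
  "muse_spectral": [
    "TemporalDeltaPower", "PrefrontalGammaPower", "TemporalThetaPower",
    "TemporalBetaPower", "TemporalGammaPower", "EngagementIndex",
    "AsymmetryIndexPrefrontal", "CLI"
  ],
  "e4_shared": [
    "max-scr", "HRV-SDNN", "HRV-RMSSD", "Max-Heart-Rate", "max-skt",
    "max-scl", "HRV-MeanNN", "HRV-ratio-LF-HF"
  ]
}
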