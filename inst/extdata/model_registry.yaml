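# Registry of the published model configurations: one entry per
# study x classification task, applying to both the Bi-LSTM and Bi-GRU
# variants (the two share identical parameter settings within each study).
#
# units: one [conv_filters, rnn_units] pair per Conv -> Bi-RNN -> AvgPool unit.
# dropout: rate between consecutive units; ~ means no dropout layer.
# incomplete: fields whose published value is missing; the entry carries the
#   documented fallback (dense width 100, dropout 0.1, 150 epochs) and
#   get_config() warns when such a config is resolved.

defaults:
  batch_size: 64
  learning_rate: 0.001
  pool_size: 2
  conv_stride: 1
  conv_padding: valid
  folds: 5

configs:
  # ---- Study 1: unfiltered full-length (23.6 s) signals --------------------
  - {study: 1, task: A-E,       units: [[32, 16], [16, 8]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 50,
     incomplete: [dropout]}
  - {study: 1, task: B-E,       units: [[32, 32], [16, 16]],
     kernel: 2, dense: [100, 50, 10],  dropout: 0.1, epochs: 100,
     incomplete: [dropout]}
  - {study: 1, task: AB-CD-E,   units: [[64, 8], [128, 4]],
     kernel: 2, dense: [80, 40, 20],   dropout: 0.1, epochs: 150,
     incomplete: [dropout]}
  - {study: 1, task: AB-C-D-E,  units: [[128, 32], [64, 16], [32, 8]],
     kernel: 2, dense: [32],           dropout: 0.1, epochs: 150,
     incomplete: [dropout]}
  - {study: 1, task: A-B-C-D-E, units: [[128, 32], [64, 16], [32, 8]],
     kernel: 2, dense: [100, 50, 25],  dropout: 0.1, epochs: 150,
     incomplete: [dropout]}

  # ---- Study 2: filtered full-length (23.6 s) signals ----------------------
  - {study: 2, task: A-E,       units: [[4, 4], [8, 8]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 50,
     incomplete: []}
  - {study: 2, task: B-E,       units: [[16, 16], [8, 8]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 100,
     incomplete: []}
  - {study: 2, task: AB-CD-E,   units: [[256, 128], [64, 64], [32, 32]],
     kernel: 2, dense: [200],          dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 2, task: AB-C-D-E,  units: [[64, 64], [32, 32], [16, 16]],
     kernel: 4, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [dense]}
  - {study: 2, task: A-B-C-D-E, units: [[128, 64], [64, 32], [32, 16]],
     kernel: 4, dense: [50],           dropout: 0.1, epochs: 150,
     incomplete: []}

  # ---- Study 3: unfiltered 11.8 s segments (2,048 samples) -----------------
  - {study: 3, task: A-E,       units: [[256, 64], [64, 32], [32, 16]],
     kernel: 2, dense: [200, 50],      dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 3, task: B-E,       units: [[256, 64], [64, 32], [32, 16]],
     kernel: 2, dense: [200, 50],      dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 3, task: AB-CD-E,   units: [[32, 16], [16, 8], [8, 4]],
     kernel: 2, dense: [100, 40],      dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 3, task: AB-C-D-E,  units: [[256, 32], [128, 32], [64, 16], [32, 8]],
     kernel: 2, dense: [200, 100],     dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 3, task: A-B-C-D-E, units: [[64, 128], [128, 64], [256, 32]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [dense]}

  # ---- Study 4: filtered 11.8 s segments (2,048 samples) -------------------
  - {study: 4, task: A-E,       units: [[16, 8], [32, 16]],
     kernel: 2, dense: [100, 50, 10],  dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 4, task: B-E,       units: [[32, 32], [64, 64], [128, 128]],
     kernel: 2, dense: [100, 50],      dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 4, task: AB-CD-E,   units: [[150, 100], [120, 50], [100, 25]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 4, task: AB-C-D-E,  units: [[32, 64], [64, 32], [128, 16], [256, 8]],
     kernel: 2, dense: [200],          dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 4, task: A-B-C-D-E, units: [[32, 16], [64, 32], [128, 64]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [dense, epochs]}

  # ---- Study 5: unfiltered 1 s segments (178 samples) ----------------------
  - {study: 5, task: A-E,       units: [[128, 64], [64, 32], [16, 16]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [dense, epochs]}
  - {study: 5, task: B-E,       units: [[128, 64], [64, 32], [32, 16]],
     kernel: 2, dense: [100],          dropout: 0.1, epochs: 150,
     incomplete: [dense, epochs]}
  - {study: 5, task: AB-CD-E,   units: [[64, 32], [32, 16]],
     kernel: 2, dense: [100, 20],      dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 5, task: AB-C-D-E,  units: [[128, 128], [64, 64]],
     kernel: 4, dense: [100, 40],      dropout: 0.1, epochs: 150,
     incomplete: [epochs]}
  - {study: 5, task: A-B-C-D-E, units: [[300, 300], [150, 150]],
     kernel: 8, dense: [100],          dropout: 0.2, epochs: 150,
     incomplete: [dense, epochs]}

  # ---- Study 6: filtered 1 s segments (178 samples) ------------------------
  - {study: 6, task: A-E,       units: [[16, 8]],
     kernel: 2, dense: [100, 10],      dropout: ~,   epochs: 50,
     incomplete: []}
  - {study: 6, task: B-E,       units: [[32, 16]],
     kernel: 2, dense: [100, 10],      dropout: ~,   epochs: 50,
     incomplete: []}
  - {study: 6, task: AB-CD-E,   units: [[16, 8], [32, 16], [64, 32]],
     kernel: 2, dense: [100, 50, 20],  dropout: 0.1, epochs: 150,
     incomplete: []}
  - {study: 6, task: AB-C-D-E,  units: [[64, 64], [128, 128]],
     kernel: 2, dense: [100],          dropout: 0.25, epochs: 100,
     incomplete: [dense]}
  - {study: 6, task: A-B-C-D-E, units: [[256, 256], [128, 128]],
     kernel: 2, dense: [100],          dropout: 0.25, epochs: 100,
     incomplete: [dense]}
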