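# Example ipchemo case configuration.
# A small spherical nodule treated with cisplatin, 50% vascular
# normalization, evaluated after a 1 h instillation.
geometry: SS            # label, or a block with shape/r_l/r_s/r_ln/r_sn
drug: cisplatin         # name, or a block with the drug_params fields
normalization: 0.5      # vascular normalization fraction in [0, 1]
necrotic_core: true
t_end: 3600             # s
# C0: 0.8               # mol/m^3, overrides the drug preset
# k_intrinsic: 3.1e-17  # m^2, overrides the tissue permeability
# bath_flat_face: false # cropped shapes only
solver:
  dt: 30                # s
  n_theta: 48
  # target_h: 2.5e-6    # m; per-geometry default when omitted
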