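# ipchemo case configuration schema

A case file is YAML read by `read_case_config()`. All physical values are
SI. Unknown keys inside `tissue` are an error; units are never guessed
(use `to_si()` when transcribing printed values).

| key | type / unit | default | meaning |
|---|---|---|---|
| `geometry` | label or block | required | `LS`,`LE`,`LT`,`SS`,`SE`,`ST`, or a block below |
| `geometry.shape` | `sphere`,`ellipsoid`,`cropped` | — | parametric shape |
| `geometry.r_l` | m | — | long-axis half-length |
| `geometry.r_s` | m | `r_l` | short-axis half-length (cropped: dome height) |
| `geometry.r_ln` | m | 0 | necrotic long half-length |
| `geometry.r_sn` | m | `r_ln` | necrotic short half-length |
| `geometry.has_necrotic_core` | bool | `r_ln > 0` | toggle the core |
| `drug` | name or block | `cisplatin` | `cisplatin`, `paclitaxel`, or explicit `drug_params` fields (`name`,`D`,`beta`,`sigma`,`P_c`,`IC50`,`C0`,`MW`) |
| `tissue` | block | baseline | overrides for any `tissue_params` field (`K`,`k_intrinsic`,`mu`,`L_p`,`S_over_V`,`P_v`,`pi_v`,`pi_i`,`c_osm`,`rho`) |
| `normalization` | fraction [0,1] | 0 | vascular normalization degree |
| `necrotic_core` | bool | true | false: core treated as viable tissue |
| `k_intrinsic` | m^2 | preset | intrinsic permeability override (recomputes K = k/mu) |
| `C0` | mol/m^3 | drug preset | instillate concentration override |
| `t_end` | s | 3600 | transient evaluation time |
| `bath_flat_face` | bool | false | cropped shapes: Dirichlet on the flat face too |
| `solver.target_h` | m | geometry default | fine cell size near surface/interface |
| `solver.n_theta` | int | 48 | angular intervals (axisymmetric meshes) |
| `solver.dt` | s | 30 | implicit time step |
| `solver.n_profile` | int | 400 | samples per axis profile |
| `solver.store_every` | int | 10 | snapshot interval in steps |
| `solver.mode` | `auto`,`radial_1d`,`axisymmetric_2d` | `auto` | discretization |
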