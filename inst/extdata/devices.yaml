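schema_version: 1
devices:
  - device_id: accuitomo170
    display_name: "3D Accuitomo 170"
    tcm: false
    dap_correction_factor: 0.76
    protocols:
      - {mode_raw: Standard, fov_diameter_cm: 4, fov_height_cm: 4, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 4.02}
      - {mode_raw: Standard, fov_diameter_cm: 6, fov_height_cm: 6, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 8.23}
      - {mode_raw: Standard, fov_diameter_cm: 10, fov_height_cm: 5, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 10.0}
      - {mode_raw: Standard, fov_diameter_cm: 8, fov_height_cm: 8, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 13.1}
      - {mode_raw: Standard, fov_diameter_cm: 10, fov_height_cm: 10, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 18.2}
      - {mode_raw: Standard, fov_diameter_cm: 14, fov_height_cm: 10, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 21.7}
      - {mode_raw: Standard, fov_diameter_cm: 17, fov_height_cm: 12, tube_voltage_kv: 90, total_exposure_mas: 87.5, nominal_recorded_dap_dgycm2: 25.6}
      - {mode_raw: High-Fidelity, fov_diameter_cm: 14, fov_height_cm: 10, tube_voltage_kv: 90, total_exposure_mas: 154, nominal_recorded_dap_dgycm2: 38.1}
      - {mode_raw: High-Fidelity, fov_diameter_cm: 17, fov_height_cm: 12, tube_voltage_kv: 90, total_exposure_mas: 154, nominal_recorded_dap_dgycm2: 45.0}
  - device_id: newtom_vgi_evo
    display_name: "Newtom VGI EVO"
    tcm: true
    dap_correction_factor: 1.0
    protocols:
      - {mode_raw: Regular scan, fov_diameter_cm: 5, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 1.23}
      - {mode_raw: Regular scan, fov_diameter_cm: 8, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 1.83}
      - {mode_raw: Regular scan, fov_diameter_cm: 10, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 2.12}
      - {mode_raw: Regular scan, fov_diameter_cm: 8, fov_height_cm: 8, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 2.23}
      - {mode_raw: Regular scan, fov_diameter_cm: 12, fov_height_cm: 8, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 3.22}
      - {mode_raw: Regular scan, fov_diameter_cm: 10, fov_height_cm: 10, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 3.31}
      - {mode_raw: Regular scan, fov_diameter_cm: 15, fov_height_cm: 12, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 4.74}
      - {mode_raw: Regular scan, fov_diameter_cm: 16, fov_height_cm: 16, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 6.16}
      - {mode_raw: Regular scan, fov_diameter_cm: 24, fov_height_cm: 19, tube_voltage_kv: 110, total_exposure_mas_min: 13, total_exposure_mas_max: 33, nominal_recorded_dap_dgycm2: 9.54}
      - {mode_raw: High-Resolution, fov_diameter_cm: 5, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 4.20}
      - {mode_raw: High-Resolution, fov_diameter_cm: 8, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 6.77}
      - {mode_raw: High-Resolution, fov_diameter_cm: 10, fov_height_cm: 5, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 7.82}
      - {mode_raw: High-Resolution, fov_diameter_cm: 8, fov_height_cm: 8, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 8.29}
      - {mode_raw: High-Resolution, fov_diameter_cm: 12, fov_height_cm: 8, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 11.3}
      - {mode_raw: High-Resolution, fov_diameter_cm: 10, fov_height_cm: 10, tube_voltage_kv: 110, total_exposure_mas_min: 30, total_exposure_mas_max: 99, nominal_recorded_dap_dgycm2: 12.5}
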