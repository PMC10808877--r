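# Bundled demonstration configuration: a 30 x 40 grid world with 150
# societies, used by the end-to-end pipeline run.
grid_n_lat: 30
grid_n_lon: 40
lat_range: [-65.0, 65.0]
lon_range: [0.0, 60.0]
years: 30
seasonality_amp: 10.0
noise_sd_temp: 1.0
noise_sd_precip: 20.0
precip_base: 80.0
elevation_scale: 1000.0
n_societies: 150
n_trait_categories: 5
beta_env: -2.0
beta_dist: -1.0
alpha_horizontal: -0.5
mu_vertical: 0.6
seed: 20260923
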