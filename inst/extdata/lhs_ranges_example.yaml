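# Example Latin-hypercube ranges over the 15 model parameters other than
# the initial populations (which have virtually no effect on end-states).
# These ranges are a package fixture chosen to span the regimes the model
# exhibits -- weak to strong mutualism, slow to fast growth -- around the
# reference setting; they are a documented example, not canonical values.
number_types_humans: [2, 30]
number_types_plants: [2, 30]
undirected_variation_humans: [0.0, 0.25]
undirected_variation_plants: [0.0, 0.25]
intrinsic_growth_rate_humans: [0.01, 0.25]
intrinsic_growth_rate_plants: [0.01, 0.25]
utility_per_capita_type_n_plants_to_humans: [0.0, 3.0]
utility_per_capita_type_1_plants_to_humans: [0.0, 3.0]
utility_per_capita_type_n_humans_to_plants: [0.0, 10.0]
utility_per_capita_type_1_humans_to_plants: [0.0, 10.0]
utility_other_to_type_n_plants: [1.0, 200.0]
utility_other_to_type_1_plants: [1.0, 200.0]
utility_other_to_type_n_humans: [1.0, 100.0]
utility_other_to_type_1_humans: [1.0, 100.0]
max_area: [100.0, 2000.0]
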