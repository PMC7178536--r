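# qams pipeline configuration
# Scalar settings only; the analyte panel and score coefficients are
# CSV tables (see default_panel() and load_fixture("table5")).

# sample preparation: 0.25 g of powder refluxed in 10 mL of methanol
sample_mass_g = 0.25
extract_volume_ml = 10
dilution_factor = 1

# peak assignment window around the expected retention offset (minutes)
tolerance_min = 0.5

# method-agreement and precision limits (percent)
re_limit = 5
rsd_limit = 3
durability_rsd_limit = 5

# grading: qualified at >= 3 mg/g total; superior above 8 mg/g total
# AND above 10% aglycone share
qualified_min = 3
superior_total = 8
superior_ratio = 10

# composite score component weights (variance fractions of the
# two-component model)
w1 = 0.62614
w2 = 0.17646

# clustering: number of groups and batches set aside as singletons
hca_k = 2
hca_exclusions = 51

seed = 1
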