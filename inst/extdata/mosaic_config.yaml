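# Packaged study configuration: one representative ridge keel and the
# surrounding level ice in July. Lengths in meters, fractions in [0, 1].
keel_depth: 3.9            # sonar survey, whole ridge
consolidated_thickness: 2.2 # drilling, n = 8
macroporosity: 0.17        # rubble macroporosity, drilling, n = 8
block_thickness: 0.3       # tape measurements
# block_length omitted -> defaults to 3.5 x block_thickness
skin_thickness: 0.1        # exterior skin per block face
bottom_thickness: 0.1      # bottom habitat layer, all ice types
fyi_draft: 1.3             # first-year level ice draft
syi_draft: 1.4             # second-year level ice draft
cover_ridge: 0.22          # areal fractions from airborne laser scanning
cover_fyi: 0.50
cover_syi: 0.28
concentrations: mosaic_concentrations.csv
seed: 1
precision: 2
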