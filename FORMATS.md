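# gastrosim file formats

All tabular files are UTF-8 CSV with a mandatory header row and dot decimal
separator. Times are minutes as floats; t = 0 is the moment the meal is
mixed with the basal SGF. Readers (`read_table()`) reject unknown columns
and report the row/column of the first invalid value. Masses assume a
density of 1 g/mL for all streams.

## psd

Binned particle-size distributions, one row per bin. Bins for one
(sample, time_min, dispersant) must be contiguous (each `bin_hi_um` equals
the next `bin_lo_um`); volume fractions are renormalized on load.

| column       | type   | constraint                      |
|--------------|--------|---------------------------------|
| sample       | text   |                                 |
| time_min     | number | >= 0                            |
| dispersant   | text   | `water` or `sds_edta`           |
| bin_lo_um    | number | > 0                             |
| bin_hi_um    | number | > bin_lo_um                     |
| volume_frac  | number | >= 0                            |

```csv
sample,time_min,dispersant,bin_lo_um,bin_hi_um,volume_frac
casein_dominant_01,0,water,0.4,0.8,0.55
casein_dominant_01,0,water,0.8,1.6,0.45
```

## retention

Observed nutrient retention. `retained_pct` may exceed 100 (up to 110) to
admit observation noise.

| column       | type   | constraint                       |
|--------------|--------|----------------------------------|
| sample       | text   |                                  |
| nutrient     | text   | `protein`, `lipid`, or `total`   |
| time_min     | number | >= 0                             |
| retained_pct | number | in [0, 110]                      |

```csv
sample,nutrient,time_min,retained_pct
casein_dominant_01,protein,0,100
casein_dominant_01,protein,20,81.2
```

## bands

Gel-densitometry band intensities (arbitrary units). A t = 0 row per band
is required for residual computation.

| column    | type   | constraint |
|-----------|--------|------------|
| sample    | text   |            |
| band      | text   |            |
| time_min  | number | >= 0       |
| intensity | number | >= 0       |

```csv
sample,band,time_min,intensity
casein_dominant_01,kappa_casein,0,1000
casein_dominant_01,kappa_casein,15,105
```

## groups

Profile-class label per sample.

| column  | type | constraint                                               |
|---------|------|----------------------------------------------------------|
| sample  | text |                                                          |
| profile | text | `casein_dominant`, `whey_dominant`, or `biopolymer_whey` |

```csv
sample,profile
casein_dominant_01,casein_dominant
```

## dilution

Explicit secretion-dilution factors, for band correction without a
simulator run.

| column   | type   | constraint |
|----------|--------|------------|
| time_min | number | >= 0       |
| factor   | number | >= 1       |

```csv
time_min,factor
0,1.0
20,1.0909
```

## timeseries (simulator output)

Long format written by `write_timeseries()`: the chyme state at every
recorded grid point plus one row per emptied aliquot (`ph` is NA for
aliquots).

```csv
sample,time_min,compartment,mass_g,protein_g,lipid_g,ph
Casein_IF_1,0,chyme,110,1.7,3.94,6.8
Casein_IF_1,20,chyme,98,1.3883,3.2177,6.44
Casein_IF_1,20,emptied,22,0.3117,0.7223,NA
```

## protocol / formula YAML

Keys mirror `digestion_protocol()` / `formula_spec()` arguments
field-for-field; unknown keys are rejected; omitted keys take the
defaults.

```yaml
# protocol.yaml
meal_mass: 100        # g
basal_sgf_mass: 10    # g, pH 3.0
sgf_flow: 0.4         # mL/min
enzyme_flow: 0.1      # mL/min
emptying_mass: 22     # g per event
emptying_interval: 20 # min
total_time: 160       # min
sieve_cutoff: 1000    # um
```

## bundle manifest (manifest.json)

Written by `write_study_bundle()`: relative file paths, provenance
(seed, generator), and — for synthetic bundles — the true generating
parameters per sample, enabling parameter-recovery checks.
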