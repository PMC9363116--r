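# Source-data tables (user-supplied)

The reproduction test for the published developmental fits expects three
CSV files here, each with columns `age,value` (one row per animal):

- `transients-in-sce-vs-age.csv` — fraction of calcium transients inside
  SCEs vs age (linear fit, reported r² = 0.78)
- `inhibiting-movements-vs-age.csv` — proportion of inhibiting movements
  vs age (sigmoid fit, reported V50 = 9.015)
- `immobility-cells-vs-age.csv` — proportion of immobility-associated
  cells vs age (sigmoid fit, reported V50 = 9.022)

These per-animal tables are distributed as source-data spreadsheets
alongside the original article and are not redistributed with this
package. Without them the corresponding test reports a failure.
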