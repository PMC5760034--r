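# fieldsync

Offline-first data collection, synchronisation and export for long-term,
individual-based field studies.

Projects that follow hundreds of marked animals for decades — the motivating
system is a banded mongoose population of ~250 individuals in 10–12 social
groups — have several fieldworkers collecting structured observations
concurrently on separate devices, far from any network. fieldsync models
that workflow end to end in R:

* **A versioned entity-attribute-value store** (`eav_store()`): every datum
  is one (entity, attribute, value) entry with a version and a dirty flag,
  persisted as a single SQLite file per device. New attribute names — whole
  new observation categories — need no schema change, and data are never
  deleted: deletion is a reserved attribute that synchronises like any edit
  and leaves everything readable.
* **A two-way replica/hub sync protocol** (`full_sync()`, `serve_hub()`):
  dirty entries are pushed one at a time with per-entry acknowledgements,
  then the replica pulls everything newer than its version list. Versions
  are assigned by the hub (first receipt = 1, each accepted update +1) and
  conflicts resolve by hub arrival order — *the last replica to sync wins* —
  never by device clocks. A sync interrupted mid-push retries to exactly the
  uninterrupted state.
* **The field protocols** (`start_visit()`, `record_weight()`,
  `record_status()`, `start_focal()`, `record_group_event()`, …): group
  composition visits with automatic 3-minute GPS tracks, weekly weighings,
  pregnancy records gated to females strictly over 10 months, mate-guard /
  escort / babysit records gated on presence, 20-minute focal follows with
  per-minute neighbour scans and pausable countdowns, and a review/edit
  surface that re-runs all gating.
* **Typed CSV export** (`export_csv()`): deterministic, byte-reproducible
  per-type tables that re-parse to exactly the stored values.
* **A seeded synthetic generator** (`simulate_population()`,
  `simulate_visit()`, `simulate_focal()`, `inject_typos()`,
  `run_scenario()`): populations, field seasons, entry errors and whole
  multi-device edit/sync scenarios, fully deterministic under a master seed.

Everything is tidyverse-shaped: query and listing surfaces return tibbles,
fitted-handle objects have `tidy()`/`glance()` methods, and sessions and
follows have `autoplot()` methods.

## A worked example

```r
library(fieldsync)

store <- simulate_population(population_spec(seed = 1))
glance(store)
#> # A tibble: 1 × 5
#>   device_tag n_entities n_entries n_dirty max_version
#>   <chr>           <int>     <int>   <int>       <int>
#> 1 T1                227      1113      1113           0
```

A synthetic population: 11 packs, 216 individuals, 1113 entries — every one
still dirty because nothing has synced yet, and every version 0 because
versions come from the hub. Visit a pack on a Monday (the weekly weighing
day) and look at its GPS track:

```r
packs <- list_packs(store)
session <- simulate_visit(store, packs$entity_id[1], as.Date("2015-01-19"), seed = 2)
gps_track(session)
#> # A tibble: 10 × 4
#>    t_seconds timestamp                   lat   lon
#>        <int> <chr>                     <dbl> <dbl>
#>  1         0 2015-01-19T08:00:00+0000 -0.192  29.9
#>  2       180 2015-01-19T08:03:00+0000 -0.191  29.9
#>  3       360 2015-01-19T08:06:00+0000 -0.191  29.9
#>  # … 7 more rows
```

Fixes at 0, 180, 360, … seconds: one at the start and one every 3 minutes —
this 30-minute visit logged 10. The weighing records are ordinary tabular
data:

```r
head(export_table(store, "weight"), 4)
#> # A tibble: 4 × 7
#>   id     session individual individual_name grams period  session_time
#>   <chr>  <chr>   <chr>      <chr>           <int> <chr>   <chr>
#> 1 T1-229 T1-228  T1-2       100              1520 morning <NA>
#> 2 T1-230 T1-228  T1-3       101              1686 morning <NA>
#> 3 T1-231 T1-228  T1-4       102              1429 morning <NA>
#> 4 T1-232 T1-228  T1-5       103              1041 morning <NA>
```

Sync against a hub (in-process here; the CLI uses a hub database file):

```r
hub <- eav_store("HUB")
endpoint <- serve_hub(hub)
full_sync(store, local_transport(endpoint))
#> <sync T1: pushed 1280, acked 1280, pulled 0>
full_sync(store, local_transport(endpoint))
#> <sync T1: pushed 0, acked 0, pulled 0>
```

Every entry was pushed and acknowledged once; an immediate repeat sync
transfers nothing in either direction. A second tablet that syncs now pulls
all 1280 entries and holds a complete backup of the hub.

A command-line front end wrapping these functions ships in
`inst/cli/fieldsync.R`:

```sh
Rscript inst/cli/fieldsync.R simulate --seed 3 --out hub.db --device HUB
Rscript inst/cli/fieldsync.R sync --db replica.db --hub hub.db
Rscript inst/cli/fieldsync.R download --hub hub.db --out snapshot.db
Rscript inst/cli/fieldsync.R export --db snapshot.db --types weight,individual --out export/
```

See `vignettes/fieldsync-methods.Rmd` for the full design: the storage and
conflict model, the gating rules, every tunable parameter, and what the
synthetic generator does and does not emulate.

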