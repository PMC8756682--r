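#!/usr/bin/env Rscript
# Step 1 -- generate the study-scale synthetic district dataset.
#
# 640 square districts on a 32 x 20 lattice, nine strongly autocorrelated
# percentage covariates, and a skilled-birth-attendance outcome generated
# under a spatial-error process (lambda = 0.7) with the reference sign
# pattern. Writes the inputs every later step consumes.
# Run from the repository root: Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(sbaspatial))

seed <- 42
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sc <- make_district_scenario("paper_shape", seed = seed)
print(sc)

write_polygons_geojson(sc$frame, file.path(out_dir, "districts.geojson"))
write_attributes(sc$table, file.path(out_dir, "attributes.csv"))
jsonlite::write_json(sc$truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("\nVariable summary (percent scale):\n")
print(round(vapply(sc$table[-1], function(v) c(mean = mean(v), sd = sd(v)),
                   numeric(2)), 1))
cat("\nWrote districts.geojson, attributes.csv, truth.json to", out_dir, "\n")
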