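#!/usr/bin/env Rscript
# Step 2 -- build the contiguity structure of the district lattice.
#
# Queen contiguity (shared boundary point) is the analysis weight scheme;
# the stricter shared-border variant is built alongside for comparison.
# Writes the queen weights as a GAL neighbor-list file.
# Run from the repository root after 01_simulate.R.

suppressPackageStartupMessages(library(sbaspatial))

frame <- read_polygons("results/data/districts.geojson")
Wq <- queen_adjacency(frame)
Wb <- shared_border_adjacency(frame)

write_gal(Wq, "results/weights.gal")

deg_q <- table(Matrix::rowSums(Wq$W))
deg_b <- table(Matrix::rowSums(Wb$W))
cat("Queen contiguity:", n_units(frame), "units,",
    Matrix::nnzero(Wq$W) / 2, "undirected links,",
    length(Wq$islands), "islands\n")
cat("  degree distribution:\n"); print(deg_q)
cat("Shared-border contiguity:", Matrix::nnzero(Wb$W) / 2,
    "undirected links\n")
cat("  degree distribution:\n"); print(deg_b)
cat("\nEvery shared-border link is also a queen link:",
    all(Wb$W@x <= 1) && Matrix::nnzero(Wq$W * Wb$W) == Matrix::nnzero(Wb$W),
    "\nWrote results/weights.gal\n")
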