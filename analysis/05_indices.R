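#!/usr/bin/env Rscript
# Stage 5 — conservation indices: for every reef cell, the total area of
# reefs reachable from it (OCI) and able to reach it (ICI) within the
# dFST threshold of 0.02, and the adaptive potential index (API): ICI
# with each contributing reef weighted by its probability of carrying
# heat-stress adapted genotypes.

source("analysis/00_config.R")

dfst_df <- read.csv(res_path("connectivity", "dfst.csv"), row.names = 1,
                    check.names = FALSE)
dfst <- as.matrix(dfst_df)
areas_df <- read.csv(res_path("features", "reef_areas.csv"))
areas <- setNames(areas_df$area_km2, areas_df$cell)[rownames(dfst)]

pa_file <- res_path("gea", "pa.csv")
pa <- if (file.exists(pa_file)) {
  pa_df <- read.csv(pa_file)
  pa_df$PA[match(rownames(dfst), pa_df$cell)]
} else NULL

idx <- index_table(dfst, areas, pa, T = 0.02, cells = rownames(dfst))
dir.create(res_path("indices"), showWarnings = FALSE)
write.csv(idx, res_path("indices", "indices.csv"), row.names = FALSE)

cat("Indices for", nrow(idx), "reef cells at dFST threshold 0.02:\n")
cat("  OCI mean", signif(mean(idx$OCI), 4), "km2, range",
    paste(signif(range(idx$OCI), 4), collapse = " - "), "\n")
cat("  ICI mean", signif(mean(idx$ICI), 4), "km2\n")
if (!all(is.na(idx$API)))
  cat("  API mean", signif(mean(idx$API), 4),
      "km2 (area weighted by PA; always <= ICI)\n")
top <- idx[order(-xtfrm(replace(idx$API, is.na(idx$API), -Inf)))[1:5], ]
cat("Highest adaptive potential cells:",
    paste(top$cell, collapse = ", "), "\n")
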