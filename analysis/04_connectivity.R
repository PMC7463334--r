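#!/usr/bin/env Rscript
# Stage 4 — connectivity: pairwise Weir-Cockerham FST between sites with
# more than 10 samples, the linear FST-by-least-cost-sea-distance
# connectivity model (against a Euclidean-distance control), and the
# predicted directional genetic separation (dFST) between all reef cells.

source("analysis/00_config.R")

sim <- simulate_seascape(CONFIG)
sites <- read.csv(res_path("simulation", "sites.csv"))
gm <- read_genotypes(res_path("simulation", "genotypes.vcf"), sites)

fst <- pairwise_fst(gm, min_n = 10)
D <- sim$sea_distance
dimnames(D) <- list(CONFIG$sites$site, CONFIG$sites$site)
cm_lcp <- fit_connectivity_model(fst, D, "least_cost")

cc <- cell_centers(CONFIG$grid)
key <- (CONFIG$sites$col - 1) * CONFIG$grid$nrow + CONFIG$sites$row
E <- as.matrix(dist(cbind(cc$x[key], cc$y[key])))
dimnames(E) <- list(CONFIG$sites$site, CONFIG$sites$site)
cm_euc <- fit_connectivity_model(fst, E, "euclidean")

print(cm_lcp); print(cm_euc)
cat("The least-cost model explains",
    sprintf("%.0f%%", 100 * cm_lcp$r_squared),
    "of the FST variation (Euclidean control:",
    sprintf("%.0f%%", 100 * cm_euc$r_squared), ") and wins by AIC:",
    signif(cm_lcp$aic, 5), "vs", signif(cm_euc$aic, 5), "\n")

reefs <- reefscape:::default_reef_cells(CONFIG$grid)
upx <- !duplicated(reefs$cell)
nodes <- site_nodes(CONFIG$grid, data.frame(row = reefs$row[upx],
                                            col = reefs$col[upx]))
Dr <- least_cost(sim$graph, nodes, nodes)
dfst <- predict_dfst(cm_lcp, Dr)
dimnames(dfst) <- list(reefs$cell[upx], reefs$cell[upx])

dir.create(res_path("connectivity"), showWarnings = FALSE)
write.csv(fst, res_path("connectivity", "fst.csv"), row.names = FALSE)
jsonlite::write_json(
  list(least_cost = cm_lcp[c("intercept", "slope", "r_squared", "aic", "n")],
       euclidean = cm_euc[c("intercept", "slope", "r_squared", "aic", "n")]),
  res_path("connectivity", "models.json"), auto_unbox = TRUE, digits = NA)
write.csv(cbind(cell = rownames(dfst), as.data.frame(dfst)),
          res_path("connectivity", "dfst.csv"), row.names = FALSE)
cat("dFST predicted for", nrow(dfst), "reef cells; off-diagonal median",
    signif(median(dfst[row(dfst) != col(dfst)]), 3), "\n")
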