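#!/usr/bin/env Rscript
# Stage 7 -- management buffer distance.
#
# The buffer around a conservation area that would exclude even the
# widest-ranging cat: the equivalent-circle diameter of the largest 100%
# MCP home range plus a 20% safety margin, rounded to 10 m.
suppressMessages(library(catroam))

cfg <- roam_config(rng_seed = 20210601L)
areas <- read.csv("results/homerange_areas.csv")
mcp_all <- areas[areas$method == "MCP" & areas$period == "all", ]
amax <- max(mcp_all$area_ha)

d <- equivalent_circle_diameter(amax)
b <- buffer_distance(amax, cfg$buffer_margin)
cat(sprintf("largest 100%% MCP: %.2f ha (%s)\n", amax,
            mcp_all$animal_id[which.max(mcp_all$area_ha)]))
cat(sprintf("equivalent-circle diameter: %d m (raw %.1f m)\n",
            d$diameter_m, d$raw_m))
cat(sprintf("buffer with %.0f%% margin: %d m\n",
            100 * cfg$buffer_margin, b$buffer_m))

write_results(data.frame(largest_mcp_ha = amax,
                         diameter_m = d$diameter_m,
                         buffer_m = b$buffer_m,
                         margin = cfg$buffer_margin),
              "results/buffer.csv", cfg)
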