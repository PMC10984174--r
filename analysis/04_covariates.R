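#!/usr/bin/env Rscript
# Stage 4 -- per-cat predictor table.
#
# Neuroticism scored from the 13 survey items (with Cronbach's alpha),
# road density summed inside a disc whose radius derives from the median
# 95% KDE home range, the major-road flag from the 100% MCP, and the
# ordinal start date.
suppressMessages(library(catroam))

cfg <- roam_config(rng_seed = 20210601L)
fixes <- read_fixes("results/data/fixes_clean.csv", cfg)
roads <- read_roads("results/data/roads.geojson")
meta <- read.csv("results/data/metadata.csv")
survey <- read.csv("results/data/survey.csv")
item_map <- read.csv("results/data/item_map.csv")
areas <- read.csv("results/homerange_areas.csv")

neuro_items <- as.matrix(survey[, item_map$item[item_map$domain ==
                                                  "neuroticism"]])
cat(sprintf("neuroticism inter-item reliability: Cronbach's alpha = %.2f\n",
            cronbach_alpha(neuro_items)))
pers <- neuroticism_score(survey, item_map)

kde95 <- areas$area_ha[areas$method == "KDE" & areas$level == 95 &
                         areas$period == "all"]
r_med <- radius_from_median_kde(kde95)
cat(sprintf("road-sampling radius from median 95%% KDE (%.3f ha): %d m\n",
            median(kde95), r_med))
cfg_road <- roam_config(rng_seed = cfg$rng_seed, road_radius = r_med)

cov <- build_covariates(fixes, roads, meta, pers, cfg_road)
write_results(cov, "results/covariates.csv", cfg_road)
cat(sprintf("covariates for %d cats; %d with a major road in the MCP; road density %0.f-%0.f m\n",
            nrow(cov), sum(cov$major_road), min(cov$road_density),
            max(cov$road_density)))
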