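#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study data set.
#
# One clustered urban landscape (66% impervious / 26% road / 6% greenspace
# / 2% agriculture), a street grid with one major road, and 12 owned cats
# tracked for 20 days at 2-60 min fix intervals with 4.8 m GPS error.
# Cats prefer impervious cover and avoid greenspace (true selection
# weights below), so every downstream stage has ground truth to recover.
# Artifacts (speed outliers, spikes, stationary indoor runs) are injected
# at known rates with labels kept aside.
suppressMessages(library(catroam))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- roam_config(rng_seed = 20210601L)

n_cats <- 12
set.seed(cfg$rng_seed)
homes <- cbind(runif(n_cats, 200, 800), runif(n_cats, 200, 800))
scenario <- sim_scenario(
  n_animals = n_cats,
  home_xy = homes,
  selection_weights = c(impervious = 3, road = 1.5, greenspace = 0.8,
                        agriculture = 0.8),
  outlier_rate = 0.01, spike_rate = 0.01, stationary_run_rate = 0.02,
  duration_days = 20, extent = 1000, patch_cells = 60,
  rng_seed = cfg$rng_seed)

sim <- simulate_dataset(scenario)
roads <- generate_roads(extent = 1000, seed = cfg$rng_seed)
svy <- simulate_survey(n_cats, seed = cfg$rng_seed)

write_landscape(sim$landscape, "results/data/landcover.asc")
write_landscape_mapping(sim$landscape, "results/data/landcover_mapping.csv")
write_roads(roads, "results/data/roads.geojson")
write_fixes(sim$observed, "results/data/fixes_raw.csv")
write_results(data.frame(animal_id = sim$observed$animal_id,
                         timestamp = format(sim$observed$t,
                                            "%Y-%m-%d %H:%M:%S"),
                         label = sim$labels),
              "results/data/truth_labels.csv", cfg)
write_results(svy$survey, "results/data/survey.csv", cfg)
write_results(svy$item_map, "results/data/item_map.csv", cfg)
meta <- data.frame(animal_id = paste0("cat", 1:n_cats),
                   sex = rep(c("M", "F"), length.out = n_cats),
                   age = round(runif(n_cats, 2, 14)),
                   desexed = TRUE,
                   home_x = homes[, 1], home_y = homes[, 2])
write_results(meta, "results/data/metadata.csv", cfg)

cat(sprintf("simulated %d cats, %d observed fixes (%d artifacts), %d road features\n",
            n_cats, nrow(sim$observed), sum(sim$labels != "clean"),
            length(roads)))
cat("landscape proportions:\n")
print(round(prop.table(table(sim$landscape$categories[sim$landscape$grid])), 3))
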