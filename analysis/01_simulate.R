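#!/usr/bin/env Rscript

## Stage 1: simulate the synthetic observation study at its default scale —
## 7 contestants with clustered latent affinities, 6 clips of template
## dialogue whose sentiment/similarity/clout track affinity, and 50
## observers completing the full forced-choice design twice per condition.
## Full data land in scratch/ (they are cheap to regenerate from the seed);
## a small overview table lands in results/.

library(convrel)
suppressMessages(library(dplyr))

SEED <- 20240901
dir.create("scratch/study", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

sim <- simulate_study(world_config(), seed = SEED)

write_transcript(sim$utterances, "scratch/study/transcript.tsv")
readr::write_tsv(sim$trials, "scratch/study/trials.tsv")
jsonlite::write_json(
  list(seed = SEED,
       affinity = sim$world$affinity,
       strengths = as.list(sim$world$strengths)),
  "scratch/study/truth.json", auto_unbox = TRUE, digits = NA)

overview <- bind_rows(
  tibble::tibble(quantity = "contestants", value = length(sim$world$roster$contestants)),
  tibble::tibble(quantity = "clips", value = max(sim$utterances$clip)),
  tibble::tibble(quantity = "observers", value = dplyr::n_distinct(sim$trials$participant)),
  tibble::tibble(quantity = "utterances", value = nrow(sim$utterances)),
  tibble::tibble(quantity = "dyadic_utterances",
                 value = sum(sim$utterances$addressee_type == "dyadic")),
  tibble::tibble(quantity = "trials", value = nrow(sim$trials)),
  tibble::tibble(quantity = "missed_trials", value = sum(is.na(sim$trials$selected))),
  sim$world$affinity |> count(cluster) |>
    transmute(quantity = paste0("dyads_", cluster), value = as.numeric(n))
)
readr::write_tsv(overview, "results/study_overview.tsv")
print(as.data.frame(overview), row.names = FALSE)

cat("\nThe world has", sum(sim$world$affinity$cluster == "friend"),
    "friend-cluster dyads (affinity near +0.7) and",
    sum(sim$world$affinity$cluster == "rival"),
    "rival-cluster dyads (near -0.7);",
    "observers choose by a softmax of affinity differences.\n")
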